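# Base identity of each codon at positions 1..3, and GC indicators,
# derived once per call from the fixed codon order.
.codonBases <- function() {
  codons <- allCodons()
  list(
    b1 = substr(codons, 1L, 1L),
    b2 = substr(codons, 2L, 2L),
    b3 = substr(codons, 3L, 3L)
  )
}

.compositionRow <- function(counts, code) {
  counts <- counts[allCodons()]
  bs <- .codonBases()
  tot <- sum(counts)
  if (tot == 0)
    stop("cannot compute composition of an empty codon tally")
  gcOf <- function(b) sum(counts[b %in% c("G", "C")]) / tot
  gc1 <- gcOf(bs$b1); gc2 <- gcOf(bs$b2); gc3 <- gcOf(bs$b3)
  # silent-capable third positions: codons of families with n_i >= 2
  silentCodons <- analysisCodons(code)
  sc <- counts[silentCodons]
  b3s <- substr(silentCodons, 3L, 3L)
  stot <- sum(sc)
  frac3s <- function(base) if (stot > 0) sum(sc[b3s == base]) / stot else NA_real_
  t3s <- frac3s("T"); c3s <- frac3s("C"); a3s <- frac3s("A"); g3s <- frac3s("G")
  data.frame(
    gc1 = gc1, gc2 = gc2, gc3 = gc3,
    gc = (gc1 + gc2 + gc3) / 3,
    gc12 = (gc1 + gc2) / 2,
    gc3s = if (stot > 0) c3s + g3s else NA_real_,
    t3s = t3s, c3s = c3s, a3s = a3s, g3s = g3s
  )
}

#' Positional GC composition per gene
#'
#' For each gene, the G+C fraction at codon positions 1, 2 and 3 over the
#' whole CDS (terminal stop codon included — the whole-CDS convention),
#' their mean \code{gc}, the first-two-position mean \code{gc12}, plus the
#' composition of synonymously variable third positions: \code{gc3s} and
#' the \code{t3s}/\code{c3s}/\code{a3s}/\code{g3s} base fractions are
#' computed only over third positions of codons belonging to families with
#' degeneracy at least 2 (Met, Trp and stops excluded), as simple base
#' fractions among those silent-capable sites.
#'
#' @param x a [CodonTable-class], a named 64-codon count vector, or a
#'   DNAStringSet / character vector of CDS (tallied internally)
#' @param code a [GeneticCode-class]
#' @return data.frame, one row per gene, columns gc1, gc2, gc3, gc, gc12,
#'   gc3s, t3s, c3s, a3s, g3s; fractions in [0, 1]
#' @examples
#' positionalComposition(countCodons("ATGGATAAATAA"))
#' @export
positionalComposition <- function(x, code = geneticCode()) {
  if (is(x, "XStringSet") || is.character(x))
    x <- codonTable(x)
  if (is(x, "CodonTable")) {
    rows <- lapply(seq_len(nrow(x@counts)),
                   function(i) .compositionRow(x@counts[i, ], code))
    out <- do.call(rbind, rows)
    rownames(out) <- rownames(x@counts)
    return(out)
  }
  .compositionRow(x, code)
}

#' Genome-level composition from pooled position tallies
#'
#' The genome value is computed from the pooled codon counts across genes
#' (codon-count-weighted), which is exactly the composition of the
#' concatenated sequences — not an unweighted mean of per-gene fractions.
#' The unweighted-mean alternative is available for sensitivity checks.
#'
#' @param x a [CodonTable-class] (or genes x 64 count matrix)
#' @param code a [GeneticCode-class]
#' @param weighting "pooled" (default) or "mean"
#' @return one-row data.frame with the same columns as
#'   [positionalComposition()]
#' @export
genomeComposition <- function(x, code = geneticCode(),
                              weighting = c("pooled", "mean")) {
  weighting <- match.arg(weighting)
  if (weighting == "pooled") {
    out <- .compositionRow(aggregateCounts(x), code)
  } else {
    per <- positionalComposition(x, code)
    out <- as.data.frame(t(colMeans(per, na.rm = TRUE)))
  }
  rownames(out) <- NULL
  out
}
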