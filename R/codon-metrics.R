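#' Per-codon usage index table: RSCU, RFSC, preferred and HF flags
#'
#' For codon \eqn{j} of amino acid \eqn{i} with family size \eqn{n_i} and
#' observed count \eqn{x_{ij}}:
#' \deqn{RSCU_{ij} = x_{ij} / \left(\frac{1}{n_i}\sum_j x_{ij}\right)}
#' \deqn{RFSC_{ij} = x_{ij} / \sum_j x_{ij}}
#' so \eqn{RSCU = RFSC \times n_i}; within each observed family RSCU sums
#' to \eqn{n_i} and RFSC sums to 1.  Families with zero total usage yield
#' missing values (NA), flagged in \code{observed}.
#'
#' Flags follow the genome-scope conventions: \code{preferred} marks
#' RSCU > 1 restricted to the 59-codon space (Met, Trp and stops never
#' preferred); \code{highFrequency} marks codons of multi-codon families
#' whose RFSC exceeds 0.60 or 1.5 times the family's uniform expectation
#' \eqn{1/n_i}.  Stop codons participate in the HF screen as the TER
#' family but are excluded from RSCU-based preferred calls.
#'
#' @param counts named 64-codon count vector (gene or genome scope;
#'   terminal stops are harmless — they only feed the TER family)
#' @param code a [GeneticCode-class]
#' @return data.frame with columns codon, aa, ni, count, rscu, rfsc,
#'   observed, preferred, highFrequency; one row per codon of every
#'   family (sense families plus TER), in codon-table order within family
#' @examples
#' cnt <- countCodons("ATGTTATTATTATTGCTTCTCTAA", includeStop = FALSE)
#' tab <- codonIndexTable(cnt)
#' subset(tab, aa == "L")
#' @export
codonIndexTable <- function(counts, code = geneticCode()) {
  counts <- counts[allCodons()]
  fams <- c(code@families, list(`*` = stopCodons(code)))
  rows <- lapply(names(fams), function(aa) {
    cs <- fams[[aa]]
    ni <- length(cs)
    x <- as.numeric(counts[cs])
    tot <- sum(x)
    rfsc <- if (tot > 0) x / tot else rep(NA_real_, ni)
    rscu <- rfsc * ni
    data.frame(codon = cs, aa = aa, ni = ni, count = x,
               rscu = rscu, rfsc = rfsc,
               observed = tot > 0, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  space59 <- analysisCodons(code)
  tab$preferred <- !is.na(tab$rscu) & tab$rscu > 1 & tab$codon %in% space59
  tab$highFrequency <- tab$ni >= 2L & !is.na(tab$rfsc) &
    (tab$rfsc > 0.60 | tab$rfsc > 1.5 / tab$ni)
  tab <- tab[order(match(tab$codon, allCodons())), ]
  rownames(tab) <- tab$codon
  tab
}

#' Relative synonymous codon usage
#'
#' Convenience wrapper around [codonIndexTable()]; see there for the
#' definition and conventions.
#'
#' @inheritParams codonIndexTable
#' @return the full codon index table (use the \code{rscu} column)
#' @export
rscu <- function(counts, code = geneticCode()) {
  codonIndexTable(counts, code)
}

#' Relative frequency of synonymous codons
#'
#' Convenience wrapper around [codonIndexTable()]; see there for the
#' definition and conventions.
#'
#' @inheritParams codonIndexTable
#' @return the full codon index table (use the \code{rfsc} column)
#' @export
rfsc <- function(counts, code = geneticCode()) {
  codonIndexTable(counts, code)
}

#' High-frequency codons of an index table
#'
#' A codon is high-frequency when its share of its synonymous family
#' (RFSC) exceeds 60\% or 1.5 times the family's uniform expectation
#' \eqn{1/n_i}.  Single-codon families (Met, Trp) cannot be HF; the three
#' stop codons compete as one TER family.
#'
#' @param table a codon index table from [codonIndexTable()]
#' @return character vector of HF codons
#' @export
highFrequencyCodons <- function(table) {
  table$codon[table$highFrequency]
}

#' Preferred codons of an index table (RSCU > 1, 59-codon space)
#'
#' @param table a codon index table from [codonIndexTable()]
#' @return character vector of preferred codons
#' @export
preferredCodons <- function(table) {
  table$codon[table$preferred]
}

#' Gene or species RSCU vectors over the 59-codon space
#'
#' Builds the matrix consumed by correspondence analysis (rows = genes)
#' or by RSCU-profile clustering and heatmaps (rows = species).  With
#' \code{mode = "aggregate"} each species row comes from RSCU of the
#' genome-aggregated codon counts (the default; avoids undefined per-gene
#' families); \code{mode = "mean"} averages per-gene RSCU vectors instead.
#' Missing entries (unobserved families) are imputed as 0 with a warning.
#'
#' @param x a [CodonTable-class] (rows = genes of one genome) or a named
#'   list of CodonTable / aggregated count vectors (rows = species)
#' @param code a [GeneticCode-class]
#' @param mode "aggregate" or "mean" (only meaningful for species rows)
#' @return numeric matrix with 59 codon columns
#' @export
rscuMatrix <- function(x, code = geneticCode(),
                       mode = c("aggregate", "mean")) {
  mode <- match.arg(mode)
  space <- analysisCodons(code)
  rowOf <- function(counts) {
    tab <- codonIndexTable(counts, code)
    setNames(tab[space, "rscu"], space)
  }
  if (is(x, "CodonTable")) {
    m <- t(apply(x@counts, 1L, rowOf))
  } else if (is.list(x)) {
    m <- t(vapply(x, function(el) {
      if (is(el, "CodonTable")) {
        if (mode == "aggregate") rowOf(aggregateCounts(el))
        else colMeans(t(apply(el@counts, 1L, rowOf)), na.rm = TRUE)
      } else rowOf(el)
    }, numeric(length(space))))
  } else {
    m <- matrix(rowOf(x), nrow = 1L, dimnames = list("genome", space))
  }
  colnames(m) <- space
  if (anyNA(m)) {
    warning("unobserved codon families: RSCU entries imputed as 0")
    m[is.na(m)] <- 0
  }
  m
}

#' Does a codon end in A or T (A or U on the RNA alphabet)?
#' @param codons character vector of DNA codons
#' @return logical vector
#' @export
endsInAT <- function(codons) {
  substr(codons, 3L, 3L) %in% c("A", "T")
}

#' Write a per-genome codon index table to TSV
#' @param table a codon index table
#' @param path output path
#' @return invisibly, the path
#' @export
writeCodonIndexTable <- function(table, path) {
  out <- table
  names(out) <- c("codon", "aa", "n_i", "count", "RSCU", "RFSC",
                  "observed", "preferred", "HF")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
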