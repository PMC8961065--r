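#' Synonymous codon usage order (SCUO) of a gene
#'
#' Entropy-based bias measure in [0, 1].  For each amino acid \eqn{i}
#' with family size \eqn{n_i \ge 2} and family count \eqn{x_i > 0}:
#' \deqn{H_i = -\sum_j p_{ij} \log p_{ij}, \quad p_{ij} = x_{ij}/x_i}
#' \deqn{O_i = (\log n_i - H_i)/\log n_i}
#' and SCUO is the composition-weighted mean
#' \eqn{\sum_i (x_i / \sum_i x_i)\, O_i} over multi-codon amino acids
#' only.  \eqn{0 \log 0 \equiv 0}; the log base cancels in \eqn{O_i} so
#' the measure is base-invariant.  Uniform usage in every observed family
#' gives 0; single-codon usage in every observed family gives 1.
#'
#' @param counts named 64-codon count vector (stop codons ignored)
#' @param code a [GeneticCode-class]
#' @return list with \code{scuo} (NA with a warning when no multi-codon
#'   family is observed) and \code{perAa} data.frame (aa, ni, xi, Hi, Oi,
#'   Fi) where Fi is the composition weight
#' @examples
#' scuo(countCodons("ATGAAAAAAAAGTAA", includeStop = FALSE))
#' @export
scuo <- function(counts, code = geneticCode()) {
  counts <- senseCounts(counts[allCodons()], code)
  fams <- codonFamilies(code, minSize = 2L)
  perAa <- do.call(rbind, lapply(names(fams), function(aa) {
    cs <- fams[[aa]]
    xi <- sum(counts[cs])
    if (xi == 0)
      return(data.frame(aa = aa, ni = length(cs), xi = 0,
                        Hi = NA_real_, Oi = NA_real_, Fi = 0))
    p <- counts[cs] / xi
    p <- p[p > 0]
    Hi <- -sum(p * log(p))
    Oi <- (log(length(cs)) - Hi) / log(length(cs))
    data.frame(aa = aa, ni = length(cs), xi = xi, Hi = Hi, Oi = Oi, Fi = 0)
  }))
  tot <- sum(perAa$xi)
  if (tot == 0) {
    warning("no multi-codon family observed; SCUO undefined")
    return(list(scuo = NA_real_, perAa = perAa))
  }
  perAa$Fi <- perAa$xi / tot
  list(scuo = sum(perAa$Fi * perAa$Oi, na.rm = TRUE), perAa = perAa)
}

#' MILC: measure independent of length and composition
#'
#' Divergence of a gene's within-family codon frequencies from a
#' reference codon usage, with a degeneracy correction.  For amino acid
#' \eqn{a} observed in the gene:
#' \deqn{M_a = 2 \sum_{j \in a} x_{aj} \ln(f_{aj} / g_{aj})}
#' with \eqn{f} the gene's and \eqn{g} the reference's within-family
#' frequencies (natural log; codons with \eqn{x_{aj} = 0} contribute 0).
#' \deqn{MILC = \frac{\sum_a M_a}{L} - c, \qquad
#'       c = \frac{\sum_a (n_a - 1)}{L}}
#' where \eqn{L} is the gene's codon count (stops excluded) and the
#' correction sums over amino acids observed in the gene.  A gene whose
#' family frequencies equal the reference exactly has
#' \eqn{\sum M_a = 0}, hence MILC \eqn{= -c}; long genes sampled from the
#' reference drift toward 0.  The expected reference is typically the
#' aggregated codon usage of the gene's own genome ("average codon usage
#' of the entire sample").
#'
#' Zero reference frequencies for codons the gene actually uses are
#' repaired by adding 0.5 to every reference codon count of the affected
#' family (the smallest intervention keeping \eqn{M_a} finite); the
#' result is flagged.
#'
#' Two baseline conventions exist in the literature for the correction
#' term: \code{convention = "zero"} (the default) uses
#' \eqn{c = \sum_a (n_a - 1)/L}, under which reference-identical genes
#' score \eqn{-c} and long reference-sampled genes score about 0;
#' \code{convention = "half"} subtracts an additional \eqn{-0.5} from the
#' correction (as coRdon does), shifting every value up by 0.5 so that
#' reference-sampled genes score about 0.5.  The divergence term is
#' identical; only the reported baseline differs.
#'
#' @param counts named 64-codon count vector for the gene
#' @param reference named 64-codon count vector of reference usage
#'   (e.g. [aggregateCounts()] of the genome)
#' @param code a [GeneticCode-class]
#' @param convention baseline convention for the correction, see above
#' @return list with \code{milc}, \code{perAa} data.frame (aa, Ma),
#'   \code{correction} c, \code{L} and \code{pseudoApplied}
#' @export
milc <- function(counts, reference, code = geneticCode(),
                 convention = c("zero", "half")) {
  convention <- match.arg(convention)
  counts <- senseCounts(counts[allCodons()], code)
  reference <- senseCounts(reference[allCodons()], code)
  L <- sum(counts)
  if (L == 0) stop("gene has no sense codons; MILC undefined")
  fams <- code@families
  pseudo <- FALSE
  rows <- lapply(names(fams), function(aa) {
    cs <- fams[[aa]]
    x <- counts[cs]
    xa <- sum(x)
    if (xa == 0) return(NULL)
    gref <- reference[cs]
    if (any(gref == 0 & x > 0)) {
      gref <- gref + 0.5
      pseudo <<- TRUE
    }
    g <- gref / sum(gref)
    f <- x / xa
    use <- x > 0
    Ma <- 2 * sum(x[use] * log(f[use] / g[use]))
    data.frame(aa = aa, na = length(cs), Ma = Ma)
  })
  perAa <- do.call(rbind, rows)
  corr <- sum(perAa$na - 1) / L
  if (convention == "half") corr <- corr - 0.5
  list(milc = sum(perAa$Ma) / L - corr,
       perAa = perAa[, c("aa", "Ma")],
       correction = corr, L = L, pseudoApplied = pseudo)
}

#' Pearson correlation between SCUO and MILC across genes
#'
#' @param scuoValues numeric vector of per-gene SCUO
#' @param milcValues numeric vector of per-gene MILC, same genes
#' @return list with \code{r}, \code{p} (two-tailed, t-based) and
#'   \code{n}; NA with a warning when fewer than 3 complete pairs or a
#'   zero-variance vector
#' @export
correlateScuoMilc <- function(scuoValues, milcValues) {
  stopifnot(length(scuoValues) == length(milcValues))
  ok <- stats::complete.cases(scuoValues, milcValues)
  x <- scuoValues[ok]; y <- milcValues[ok]
  if (length(x) < 3L) {
    warning("need at least 3 paired genes")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-gene expression-bias table (SCUO and MILC) for a genome
#'
#' @param ct a [CodonTable-class]
#' @param reference reference counts for MILC; defaults to the genome's
#'   own aggregated usage
#' @param code a [GeneticCode-class]
#' @return data.frame with columns gene, L, scuo, milc
#' @export
expressionTable <- function(ct, reference = NULL, code = geneticCode()) {
  stopifnot(is(ct, "CodonTable"))
  if (is.null(reference)) reference <- aggregateCounts(ct)
  m <- ct@counts
  res <- lapply(seq_len(nrow(m)), function(i) {
    cnt <- m[i, ]
    s <- suppressWarnings(scuo(cnt, code)$scuo)
    mv <- milc(cnt, reference, code)
    data.frame(gene = rownames(m)[i], L = mv$L, scuo = s, milc = mv$milc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
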