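#' Observed effective number of codons (ENc)
#'
#' Wright's homozygosity estimator.  For each amino acid with family size
#' \eqn{n_i \ge 2} and total family count \eqn{n > 1}, the codon
#' homozygosity is
#' \deqn{\hat F = (n \sum_j p_j^2 - 1) / (n - 1)}
#' with \eqn{p_j} the within-family codon frequencies.  \eqn{\hat F} is
#' averaged within each degeneracy class \eqn{k \in \{2, 3, 4, 6\}}
#' (under the standard code: 9 two-fold, 1 three-fold (Ile), 5 four-fold
#' and 3 six-fold families), and
#' \deqn{ENc = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6.}
#' Missing-class fallback: an absent \eqn{\bar F_3} defaults to
#' \eqn{(\bar F_2 + \bar F_4)/2}; any other missing class term uses the
#' mean of the available class homozygosities.  The result is clamped to
#' the theoretical range [2, 61]; uniform synonymous usage with large
#' counts gives ENc near 61, extreme bias drives it toward the number of
#' amino acids.
#'
#' @param counts named 64-codon count vector (stop codons are ignored)
#' @param code a [GeneticCode-class]
#' @return list with \code{enc} (NA when no family is estimable),
#'   \code{fBarByClass} (named mean homozygosity per degeneracy class)
#'   and \code{nMissingClasses}
#' @examples
#' encObserved(countCodons("ATGTTATTGCTTCTCCTACTGTAA", includeStop = FALSE))
#' @export
encObserved <- function(counts, code = geneticCode()) {
  counts <- senseCounts(counts[allCodons()], code)
  fams <- codonFamilies(code, minSize = 2L)
  classes <- sort(unique(vapply(fams, length, integer(1))))
  fHat <- vapply(fams, function(cs) {
    n <- sum(counts[cs])
    if (n <= 1) return(NA_real_)
    p <- counts[cs] / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  deg <- vapply(fams, length, integer(1))
  fBar <- vapply(classes, function(k) {
    v <- fHat[deg == k]
    v <- v[!is.na(v) & v > 0]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  names(fBar) <- as.character(classes)
  nFam <- vapply(classes, function(k) sum(deg == k), integer(1))
  if (all(is.na(fBar))) {
    warning("no estimable synonymous family; ENc undefined")
    return(list(enc = NA_real_, fBarByClass = fBar,
                nMissingClasses = sum(is.na(fBar))))
  }
  fUse <- fBar
  if (is.na(fUse["3"]) && !is.na(fUse["2"]) && !is.na(fUse["4"]))
    fUse["3"] <- (fUse["2"] + fUse["4"]) / 2
  still <- is.na(fUse)
  if (any(still)) fUse[still] <- mean(fUse[!still])
  enc <- 2 + sum(nFam / fUse)
  enc <- min(max(enc, 2), 61)
  list(enc = enc, fBarByClass = fBar, nMissingClasses = sum(is.na(fBar)))
}

#' Expected ENc as a function of GC3s
#'
#' The null expectation when composition alone (no selection) drives
#' codon usage, with \eqn{S} the GC content of synonymously variable
#' third positions:
#' \deqn{ENc = 2 + S + \frac{29}{S^2 + (1 - S)^2}.}
#' The curve is maximal at \eqn{S = 0.5} where it equals 60.5.
#'
#' @param gc3s numeric vector of GC3s fractions in [0, 1]
#' @return numeric vector of expected ENc values
#' @examples
#' encExpected(c(0, 0.5, 1))  # 31, 60.5, 32
#' @export
encExpected <- function(gc3s) {
  if (any(is.na(gc3s)) || any(gc3s < 0) || any(gc3s > 1))
    stop("gc3s must lie in [0, 1]")
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Parity-rule-2 coordinates of a gene
#'
#' Third-position purine/pyrimidine balance between the two DNA strands:
#' \eqn{x = G_3/(G_3 + C_3)} and \eqn{y = A_3/(A_3 + T_3)}, with the
#' tallies restricted by default to codons of four-fold degenerate
#' families (the standard PR2-bias convention, where third-position
#' substitutions are always silent); \code{familyMode = "all"} tallies
#' every codon's third position instead.  The point (0.5, 0.5) marks no
#' strand asymmetry.
#'
#' @param counts named 64-codon count vector
#' @param code a [GeneticCode-class]
#' @param familyMode "fourfold" (default) or "all"
#' @return list with \code{x}, \code{y} (NA when a denominator is zero)
#'   and the four third-position tallies
#' @export
pr2Point <- function(counts, code = geneticCode(),
                     familyMode = c("fourfold", "all")) {
  familyMode <- match.arg(familyMode)
  counts <- counts[allCodons()]
  if (familyMode == "fourfold") {
    fams <- code@families[code@degeneracy == 4L]
    cs <- unlist(fams, use.names = FALSE)
  } else {
    cs <- allCodons()
  }
  b3 <- substr(cs, 3L, 3L)
  tal <- vapply(c("A", "T", "G", "C"),
                function(b) sum(counts[cs[b3 == b]]), numeric(1))
  x <- if (tal["G"] + tal["C"] > 0) tal[["G"]] / (tal[["G"]] + tal[["C"]]) else NA_real_
  y <- if (tal["A"] + tal["T"] > 0) tal[["A"]] / (tal[["A"]] + tal[["T"]]) else NA_real_
  list(x = x, y = y, a3 = tal[["A"]], t3 = tal[["T"]],
       g3 = tal[["G"]], c3 = tal[["C"]])
}

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of per-gene GC12 on GC3 with the Pearson
#' correlation and its two-tailed t-based p-value (n - 2 df).  A slope
#' near 1 with significant correlation indicates mutation pressure
#' dominating codon usage; a slope near 0 indicates selection.
#'
#' @param composition data.frame with columns \code{gc12} and \code{gc3}
#'   (one row per gene), e.g. from [positionalComposition()]
#' @return list with slope, intercept, pearsonR, pValue, nGenes,
#'   gc12Range and gc3Range; slope/r are NA (with a warning) when GC3
#'   has zero variance or fewer than 3 genes are usable
#' @export
neutralityFit <- function(composition) {
  ok <- stats::complete.cases(composition[, c("gc12", "gc3")])
  d <- composition[ok, , drop = FALSE]
  n <- nrow(d)
  empty <- list(slope = NA_real_, intercept = NA_real_,
                pearsonR = NA_real_, pValue = NA_real_, nGenes = n,
                gc12Range = range(d$gc12), gc3Range = range(d$gc3))
  if (n < 3L) {
    warning("neutrality fit needs at least 3 genes")
    return(empty)
  }
  if (sd(d$gc3) == 0) {
    warning("GC3 has zero variance; neutrality slope undefined")
    return(empty)
  }
  fit <- lm(gc12 ~ gc3, data = d)
  ct <- suppressWarnings(cor.test(d$gc3, d$gc12, method = "pearson"))
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       pearsonR = unname(ct$estimate),
       pValue = ct$p.value,
       nGenes = n,
       gc12Range = range(d$gc12),
       gc3Range = range(d$gc3))
}
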