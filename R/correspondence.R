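#' Correspondence analysis of a gene x codon RSCU matrix
#'
#' Classical (chi-square metric) correspondence analysis, run by default
#' on the genes x 59 RSCU matrix treated as a nonnegative data table (the
#' CodonW "COA on RSCU" mode); \code{mode = "counts"} accepts a raw count
#' matrix for sensitivity analysis.  The table is scaled to grand total 1,
#' standardized residuals \eqn{(p_{ij} - r_i c_j)/\sqrt{r_i c_j}} are
#' decomposed by SVD, and principal coordinates are returned for rows and
#' columns.  Per-axis inertia fractions are \eqn{\sigma_k^2 / \sum
#' \sigma^2} over all non-trivial axes (at most \eqn{\min(rows, cols) -
#' 1}).  Axis sign is fixed by making the largest-magnitude column
#' loading of each axis positive.  Missing entries are imputed as 0; a
#' constant matrix yields a zero-axis result with a warning.
#'
#' @param m numeric matrix, genes x codons (RSCU values or counts);
#'   rows/columns with zero margin are dropped with a warning
#' @param axes number of axes to keep in the coordinate matrices
#' @param mode "rscu" or "counts" (informational; the decomposition is
#'   identical, the choice is about what you feed in)
#' @return a [CoaResult-class]
#' @examples
#' set.seed(1)
#' m <- matrix(rexp(20), 4, 5, dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' coaRscu(m, axes = 2)
#' @export
coaRscu <- function(m, axes = 4L, mode = c("rscu", "counts")) {
  mode <- match.arg(mode)
  m[is.na(m)] <- 0
  if (any(m < 0)) stop("correspondence analysis requires a nonnegative table")
  rk <- rowSums(m); ck <- colSums(m)
  if (any(rk == 0) || any(ck == 0)) {
    warning("dropping rows/columns with zero margin")
    m <- m[rk > 0, ck > 0, drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least a 2 x 2 table after dropping empty margins")
  P <- m / sum(m)
  r <- rowSums(P); cc <- colSums(P)
  E <- outer(r, cc)
  S <- (P - E) / sqrt(E)
  sv <- svd(S)
  tol <- max(dim(m)) * max(sv$d, 1) * .Machine$double.eps * 100
  nontrivial <- sv$d > tol
  d <- sv$d[nontrivial]
  maxAxes <- min(nrow(m), ncol(m)) - 1L
  if (length(d) > maxAxes) d <- d[seq_len(maxAxes)]
  if (!length(d)) {
    warning("no non-trivial axis: the table carries no variation")
    return(new("CoaResult",
               rowCoords = matrix(0, nrow(m), 0, dimnames = list(rownames(m), NULL)),
               colCoords = matrix(0, ncol(m), 0, dimnames = list(colnames(m), NULL)),
               inertiaFraction = numeric(0), singularValues = numeric(0),
               axesKept = 0L))
  }
  k <- min(as.integer(axes), length(d))
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  # principal coordinates
  F <- sweep(U, 1L, sqrt(r), "/") %*% diag(d[seq_len(k)], k)
  G <- sweep(V, 1L, sqrt(cc), "/") %*% diag(d[seq_len(k)], k)
  for (j in seq_len(k)) {
    lead <- which.max(abs(G[, j]))
    if (G[lead, j] < 0) { G[, j] <- -G[, j]; F[, j] <- -F[, j] }
  }
  dimnames(F) <- list(rownames(m), paste0("axis", seq_len(k)))
  dimnames(G) <- list(colnames(m), paste0("axis", seq_len(k)))
  new("CoaResult",
      rowCoords = F, colCoords = G,
      inertiaFraction = d^2 / sum(d^2),
      singularValues = d,
      axesKept = as.integer(k))
}
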