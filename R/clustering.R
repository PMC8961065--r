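#' Squared Euclidean distance matrix between species RSCU profiles
#'
#' \eqn{d(i, j) = \sum_c (RSCU_{ic} - RSCU_{jc})^2} over the 59-codon
#' space.  Squared Euclidean distances are a dissimilarity, not a metric
#' (no triangle inequality), and are fed to the linkage unmodified —
#' the SPSS convention for RSCU-profile clustering.  Missing entries are
#' imputed as 0 with a warning.
#'
#' @param profiles species x codon numeric matrix (e.g. [rscuMatrix()]
#'   of a list of genomes)
#' @return symmetric numeric matrix with zero diagonal, labelled by the
#'   profile rownames
#' @export
rscuDistanceMatrix <- function(profiles) {
  if (anyNA(profiles)) {
    warning("missing RSCU entries imputed as 0")
    profiles[is.na(profiles)] <- 0
  }
  d <- as.matrix(stats::dist(profiles, method = "euclidean"))^2
  dimnames(d) <- list(rownames(profiles), rownames(profiles))
  d
}

#' Between-groups (unweighted average) linkage clustering
#'
#' Agglomerative clustering that repeatedly merges the pair of clusters
#' with the smallest mean inter-cluster dissimilarity (the SPSS
#' "intergroup linkage" method, i.e. UPGMA on the supplied
#' dissimilarities).  Labels are sorted lexicographically before
#' clustering, which makes the result deterministic and invariant to the
#' input ordering of leaves, including under ties.
#'
#' @param dm symmetric dissimilarity matrix with labels (e.g. from
#'   [rscuDistanceMatrix()]); n >= 2 leaves required
#' @return an object of class \code{hclust}
#' @examples
#' d <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' hc <- averageLinkage(d)
#' hc$height  # 1, 4.5
#' @export
averageLinkage <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (nrow(dm) < 2L) stop("clustering needs at least 2 leaves")
  labs <- rownames(dm)
  if (is.null(labs)) labs <- rownames(dm) <- colnames(dm) <- paste0("S", seq_len(nrow(dm)))
  ord <- order(labs)
  dm <- dm[ord, ord, drop = FALSE]
  stats::hclust(as.dist(dm), method = "average")
}

#' Export a dendrogram as a newick string
#'
#' Ultrametric-style branch lengths: each merge sits at half its linkage
#' height, so two leaves merged at height \eqn{h} get branches of
#' \eqn{h/2} each.  Labels are escaped per newick conventions by
#' [ape::write.tree()].
#'
#' @param hc an \code{hclust} object (e.g. from [averageLinkage()])
#' @return a newick string, terminated by ";"
#' @export
toNewick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}

#' Leaf bipartition at the dendrogram root
#'
#' The two leaf sets separated by the final (root) merge — the package's
#' clade-level summary of an RSCU clustering, reported as label sets and
#' free of any taxonomic claim.
#'
#' @param hc an \code{hclust} object
#' @return list of two character vectors of leaf labels
#' @export
rootPartition <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$labels)
  members <- function(node) {
    if (node < 0) return(hc$labels[-node])
    unlist(lapply(hc$merge[node, ], members))
  }
  top <- hc$merge[n - 1L, ]
  list(sort(members(top[1L])), sort(members(top[2L])))
}
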