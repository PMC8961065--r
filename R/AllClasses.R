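#' @import methods
#' @importFrom stats as.dist coef complete.cases cor.test dist hclust lm
#'   runif rnorm sd setNames ave
#' @importFrom utils write.table read.table head
NULL

#' GeneticCode: codon-to-amino-acid map with synonymous family structure
#'
#' Holds the translation table together with the derived structures every
#' codon-usage statistic needs: the synonymous families (amino acid ->
#' ordered codon vector) and their degeneracy \eqn{n_i} (family size).
#' Under the standard code, Met (ATG) and Trp (TGG) are single-codon
#' families and 59 codons remain once those two and the three stop codons
#' are removed; that 59-codon space is used for preferred-codon calls,
#' correspondence analysis and RSCU-profile clustering.
#'
#' @slot tableId identifier of the translation table ("standard" or
#'   "plastid"; both share the same codon -> amino-acid map, they differ
#'   only in initiation codons which play no role here).
#' @slot codonToAa named character vector of length 64 mapping DNA codons
#'   to one-letter amino-acid symbols, with "*" for stop.
#' @slot families named list: amino-acid symbol -> ordered codon vector.
#'   Ser, Leu and Arg are kept as single six-fold families (the CodonW
#'   convention), not split into 2+4 subfamilies.
#' @slot degeneracy named integer vector: amino acid -> family size n_i.
#'
#' @seealso [geneticCode()], [codonFamilies()], [analysisCodons()]
#' @export
setClass("GeneticCode",
  representation(
    tableId   = "character",
    codonToAa = "character",
    families  = "list",
    degeneracy = "integer"
  )
)

setValidity("GeneticCode", function(object) {
  msg <- character(0)
  if (length(object@codonToAa) != 64L)
    msg <- c(msg, "codonToAa must map exactly 64 codons")
  nStop <- sum(object@codonToAa == "*")
  if (sum(object@degeneracy) + nStop != 64L)
    msg <- c(msg, "sum of family sizes plus stop codons must equal 64")
  if (!identical(sort(names(object@families)), sort(names(object@degeneracy))))
    msg <- c(msg, "families and degeneracy must be keyed by the same amino acids")
  if (length(msg)) msg else TRUE
})

#' CodonTable: per-gene 64-codon occurrence matrix
#'
#' The central count container: one row per coding sequence, one column per
#' codon (all 64, in TCAG order), holding the frame-0 triplet tallies of
#' the full CDS including its terminal stop codon.  Family-based statistics
#' (RSCU, RFSC, ENc, SCUO, MILC) ignore the stop columns by construction,
#' so a single matrix serves both the whole-CDS GC conventions and the
#' 59-codon synonymous space.
#'
#' @slot counts integer matrix, genes x 64 codons; rownames are gene ids.
#' @slot species character scalar tag for the genome the genes belong to.
#' @slot len integer vector of codon counts per gene (row sums).
#'
#' @seealso [codonTable()], [aggregateCounts()]
#' @export
setClass("CodonTable",
  representation(
    counts  = "matrix",
    species = "character",
    len     = "integer"
  )
)

setValidity("CodonTable", function(object) {
  msg <- character(0)
  if (ncol(object@counts) != 64L)
    msg <- c(msg, "counts must have 64 codon columns")
  if (is.null(rownames(object@counts)) ||
      anyDuplicated(rownames(object@counts)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (any(object@counts < 0))
    msg <- c(msg, "codon counts must be non-negative")
  if (length(object@len) != nrow(object@counts))
    msg <- c(msg, "len must have one entry per gene")
  if (length(msg)) msg else TRUE
})

#' FilterReport: accounting of the five-rule CDS quality filter
#'
#' Each input sequence is either retained or charged to the FIRST rule it
#' fails, so \code{nInput = nRetained + sum(rejectedByRule)} always holds.
#'
#' @slot nInput number of sequences examined.
#' @slot nRetained number of sequences that passed every rule.
#' @slot rejectedByRule named integer vector of per-rule rejection counts.
#' @slot rejectedIds data.frame with columns \code{id} and \code{rule}.
#'
#' @seealso [filterCds()], [writeFilterReport()]
#' @export
setClass("FilterReport",
  representation(
    nInput        = "integer",
    nRetained     = "integer",
    rejectedByRule = "integer",
    rejectedIds   = "data.frame"
  )
)

setValidity("FilterReport", function(object) {
  if (object@nInput != object@nRetained + sum(object@rejectedByRule))
    return("nInput must equal nRetained + total rejections")
  if (nrow(object@rejectedIds) != sum(object@rejectedByRule))
    return("rejectedIds must list one row per rejected sequence")
  TRUE
})

#' CoaResult: correspondence analysis of a gene x codon RSCU matrix
#'
#' @slot rowCoords principal coordinates of genes (rows x kept axes).
#' @slot colCoords principal coordinates of codons (columns x kept axes).
#' @slot inertiaFraction per-axis fractions of total inertia over ALL
#'   non-trivial axes (sums to 1 when any variation exists).
#' @slot singularValues singular values of the standardized residual matrix.
#' @slot axesKept number of axes retained in the coordinate matrices.
#'
#' @seealso [coaRscu()]
#' @export
setClass("CoaResult",
  representation(
    rowCoords       = "matrix",
    colCoords       = "matrix",
    inertiaFraction = "numeric",
    singularValues  = "numeric",
    axesKept        = "integer"
  )
)

setValidity("CoaResult", function(object) {
  if (length(object@inertiaFraction) &&
      (any(object@inertiaFraction < -1e-12) ||
       any(object@inertiaFraction > 1 + 1e-12)))
    return("inertia fractions must lie in [0, 1]")
  TRUE
})
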