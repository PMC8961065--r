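#' @describeIn GeneticCode compact console display
#' @param object a GeneticCode
#' @export
setMethod("show", "GeneticCode", function(object) {
  cat("GeneticCode <", object@tableId, ">\n", sep = "")
  cat("  ", length(object@families), " amino-acid families, ",
      sum(object@codonToAa == "*"), " stop codons\n", sep = "")
  cat("  degeneracy classes:",
      paste(sprintf("%d-fold x%d", as.integer(names(table(object@degeneracy))),
                    as.integer(table(object@degeneracy))), collapse = ", "),
      "\n")
  invisible(object)
})

#' @describeIn CodonTable compact console display
#' @param object a CodonTable
#' @export
setMethod("show", "CodonTable", function(object) {
  cat("CodonTable for '", object@species, "': ",
      nrow(object@counts), " genes, ",
      sum(object@counts), " codons\n", sep = "")
  invisible(object)
})

#' @describeIn FilterReport compact console display
#' @param object a FilterReport
#' @export
setMethod("show", "FilterReport", function(object) {
  cat("CDS filter report: ", object@nRetained, "/", object@nInput,
      " retained\n", sep = "")
  rej <- object@rejectedByRule[object@rejectedByRule > 0]
  if (length(rej))
    cat("  rejected:", paste(names(rej), rej, sep = "=", collapse = ", "), "\n")
  invisible(object)
})

#' @describeIn CoaResult compact console display
#' @param object a CoaResult
#' @export
setMethod("show", "CoaResult", function(object) {
  cat("Correspondence analysis: ", nrow(object@rowCoords), " genes, ",
      nrow(object@colCoords), " codons, ", object@axesKept, " axes kept\n",
      sep = "")
  k <- min(4L, length(object@inertiaFraction))
  if (k > 0)
    cat("  inertia: ",
        paste(sprintf("axis%d %.2f%%", seq_len(k),
                      100 * object@inertiaFraction[seq_len(k)]),
              collapse = ", "), "\n", sep = "")
  invisible(object)
})

#' Number of genes in a CodonTable
#' @param x a CodonTable
#' @return integer gene count
#' @export
nGenes <- function(x) {
  stopifnot(is(x, "CodonTable"))
  nrow(x@counts)
}

#' Extract the genes x 64 codon count matrix
#' @param x a CodonTable
#' @return integer matrix with gene rownames and codon colnames
#' @export
countMatrix <- function(x) {
  stopifnot(is(x, "CodonTable"))
  x@counts
}

#' Species tag of a CodonTable
#' @param x a CodonTable
#' @return character scalar
#' @export
speciesTag <- function(x) {
  stopifnot(is(x, "CodonTable"))
  x@species
}

#' Per-gene codon totals of a CodonTable
#' @param x a CodonTable
#' @return named integer vector (codons per gene)
#' @export
geneLengths <- function(x) {
  stopifnot(is(x, "CodonTable"))
  setNames(x@len, rownames(x@counts))
}

#' Per-rule rejection counts from a FilterReport
#' @param x a FilterReport
#' @return named integer vector
#' @export
rejectedByRule <- function(x) {
  stopifnot(is(x, "FilterReport"))
  x@rejectedByRule
}

#' Axis inertia fractions from a CoaResult
#' @param x a CoaResult
#' @return numeric vector over all non-trivial axes (sums to 1)
#' @export
inertiaFractions <- function(x) {
  stopifnot(is(x, "CoaResult"))
  x@inertiaFraction
}
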