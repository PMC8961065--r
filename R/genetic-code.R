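#' All 64 DNA codons in TCAG order
#'
#' @return character vector of the 64 codons, first position varying
#'   slowest, bases ordered T, C, A, G (the classical codon-table order).
#' @export
allCodons <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0
  )))
}

#' Construct a genetic code with synonymous family structure
#'
#' Builds a [GeneticCode-class] from Biostrings' translation tables.  The
#' standard code (table 1) matches the CodonW convention used throughout:
#' Ser, Leu and Arg are single six-fold families, Met and Trp are
#' singletons, and three stop codons (TAA, TAG, TGA) are excluded from all
#' families.  The plastid/bacterial code (table 11) has the identical
#' codon -> amino-acid map (it differs only in initiation codons) and is
#' accepted as an alias.
#'
#' @param tableId "standard" (default) or "plastid".
#' @return a [GeneticCode-class] object
#' @examples
#' gc <- geneticCode()
#' length(analysisCodons(gc))  # 59
#' @export
geneticCode <- function(tableId = c("standard", "plastid")) {
  tableId <- match.arg(tableId)
  ncbiId <- if (tableId == "standard") "1" else "11"
  map <- Biostrings::getGeneticCode(ncbiId)
  codons <- allCodons()
  codonToAa <- setNames(unname(map[codons]), codons)
  .makeGeneticCode(tableId, codonToAa)
}

#' Load a genetic code from a two-column codon / amino-acid file
#'
#' Plain-text interface for non-default codes: whitespace-separated
#' columns, first the codon (DNA alphabet), second the one-letter amino
#' acid or "*" for stop.  All 64 codons must be present.
#'
#' @param path file path
#' @param tableId identifier recorded on the resulting object
#' @return a [GeneticCode-class]
#' @export
readGeneticCode <- function(path, tableId = "custom") {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("codon", "aa"))
  tab$codon <- toupper(tab$codon)
  if (!setequal(tab$codon, allCodons()))
    stop("genetic-code file must define all 64 codons exactly once")
  codonToAa <- setNames(tab$aa, tab$codon)[allCodons()]
  .makeGeneticCode(tableId, codonToAa)
}

.makeGeneticCode <- function(tableId, codonToAa) {
  sense <- codonToAa[codonToAa != "*"]
  families <- split(names(sense), sense)
  # keep codon-table order within each family
  families <- lapply(families, function(cs) cs[order(match(cs, allCodons()))])
  degeneracy <- vapply(families, length, integer(1))
  new("GeneticCode",
      tableId = tableId,
      codonToAa = codonToAa,
      families = families,
      degeneracy = degeneracy)
}

#' Synonymous families of a genetic code
#' @param code a [GeneticCode-class]
#' @param minSize keep only families with at least this many codons
#' @return named list amino acid -> codon vector
#' @export
codonFamilies <- function(code, minSize = 1L) {
  code@families[code@degeneracy >= minSize]
}

#' Stop codons of a genetic code
#' @param code a [GeneticCode-class]
#' @return character vector (TAA, TAG, TGA under the standard code)
#' @export
stopCodons <- function(code) {
  names(code@codonToAa)[code@codonToAa == "*"]
}

#' The 59-codon synonymous analysis space
#'
#' Sense codons minus the single-codon families (ATG/Met, TGG/Trp) and the
#' stop codons; the space used for preferred-codon calls, gene-level RSCU
#' vectors in correspondence analysis and RSCU-profile clustering.
#'
#' @param code a [GeneticCode-class]
#' @return character vector of codons, in codon-table order
#' @export
analysisCodons <- function(code) {
  multi <- unlist(codonFamilies(code, minSize = 2L), use.names = FALSE)
  multi[order(match(multi, allCodons()))]
}

#' Degeneracy (family size) of each codon
#' @param code a [GeneticCode-class]
#' @return named integer vector over the 64 codons; NA for stop codons
#' @export
codonDegeneracy <- function(code) {
  d <- code@degeneracy[code@codonToAa]
  names(d) <- names(code@codonToAa)
  d
}

#' Tally the codons of a single coding sequence
#'
#' Non-overlapping frame-0 triplets of a filtered CDS.  With
#' \code{includeStop = FALSE} the terminal stop codon (if present) is
#' dropped from both the tally and the total, matching the convention for
#' family-based indices; GC-composition work keeps the whole CDS
#' (\code{includeStop = TRUE}, the default).
#'
#' @param seq a character scalar, DNAString or length-1 DNAStringSet over
#'   \{A,C,G,T\}, length a multiple of 3
#' @param includeStop logical; keep the terminal stop codon?
#' @param code a [GeneticCode-class] used to recognise stop codons
#' @return named integer vector over the 64 codons
#' @export
countCodons <- function(seq, includeStop = TRUE, code = geneticCode()) {
  s <- .asSeqChar(seq)
  n <- nchar(s)
  if (n == 0L || n %% 3L != 0L)
    stop("sequence length must be a positive multiple of 3")
  cod <- substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  if (!includeStop && cod[length(cod)] %in% stopCodons(code))
    cod <- cod[-length(cod)]
  tab <- table(factor(cod, levels = allCodons()))
  setNames(as.integer(tab), allCodons())
}

.asSeqChar <- function(seq) {
  if (is(seq, "XStringSet")) {
    stopifnot(length(seq) == 1L)
    seq <- seq[[1L]]
  }
  if (is(seq, "XString")) seq <- as.character(seq)
  stopifnot(is.character(seq), length(seq) == 1L)
  toupper(seq)
}

#' Build a CodonTable from a set of coding sequences
#'
#' @param cds a DNAStringSet (or named character vector) of filtered CDS
#' @param species genome tag stored on the table
#' @return a [CodonTable-class] (counts include terminal stop codons)
#' @examples
#' cds <- Biostrings::DNAStringSet(c(g1 = "ATGGATAAATAA"))
#' codonTable(cds, species = "toy")
#' @export
codonTable <- function(cds, species = "") {
  if (is.character(cds)) cds <- Biostrings::DNAStringSet(cds)
  seqs <- as.character(cds)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("gene_", seq_along(seqs))
  counts <- t(vapply(seqs, countCodons, integer(64L), includeStop = TRUE))
  rownames(counts) <- ids
  colnames(counts) <- allCodons()
  new("CodonTable", counts = counts, species = species,
      len = as.integer(rowSums(counts)))
}

#' Aggregate codon counts to genome scope
#'
#' Elementwise sum of per-gene counts; totals add.
#'
#' @param x a [CodonTable-class], a list of named 64-codon count vectors,
#'   or a genes x 64 matrix
#' @return named integer (or numeric) vector over the 64 codons
#' @export
aggregateCounts <- function(x) {
  if (is(x, "CodonTable")) x <- x@counts
  if (is.list(x) && !is.data.frame(x)) {
    if (!length(x)) return(setNames(integer(64L), allCodons()))
    x <- do.call(rbind, lapply(x, function(v) v[allCodons()]))
  }
  if (is.null(dim(x))) return(x[allCodons()])
  out <- colSums(x[, allCodons(), drop = FALSE])
  if (all(out == round(out))) out <- as.integer(round(out))
  setNames(out, allCodons())
}

#' Drop terminal-stop contributions from aggregated counts
#'
#' Family statistics operate on stop-free counts; since every filtered CDS
#' carries exactly one terminal stop, zeroing the stop columns of a
#' whole-CDS tally recovers the stop-free counts exactly.
#'
#' @param counts named 64-codon vector
#' @param code a [GeneticCode-class]
#' @return the counts with stop-codon entries set to zero
#' @export
senseCounts <- function(counts, code = geneticCode()) {
  counts[stopCodons(code)] <- 0L
  counts
}
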