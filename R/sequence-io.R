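#' Read a multi-record CDS FASTA file
#'
#' Reads unfiltered records: lowercase is uppercased, ambiguity codes and
#' other non-ACGT characters pass through untouched (the quality filter
#' decides their fate).  The header token before the first whitespace
#' becomes the record id; duplicated ids are disambiguated by appending an
#' ordinal suffix.  An NCBI-style \code{[gene=...]} qualifier in the
#' header, when present, is captured as the gene name.
#'
#' @param path FASTA file path
#' @param species species tag attached to every record
#' @return a BStringSet with \code{mcols} columns \code{geneName} and
#'   \code{species}; empty set (with a warning) for an empty file
#' @export
readCdsFasta <- function(path, species = "") {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) {
    warning("no FASTA records in ", path)
    return(.annotateCds(Biostrings::BStringSet(), character(0),
                        character(0), species))
  }
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  ids <- .disambiguateIds(ids)
  geneName <- ifelse(grepl("\\[gene=([^]]+)\\]", headers),
                     sub(".*\\[gene=([^]]+)\\].*", "\\1", headers), "")
  seqs <- toupper(as.character(x))
  .annotateCds(Biostrings::BStringSet(seqs), ids, geneName, species)
}

.disambiguateIds <- function(ids) {
  if (!anyDuplicated(ids)) return(ids)
  ave <- stats::ave(seq_along(ids), ids, FUN = seq_along)
  dup <- ids %in% ids[duplicated(ids)]
  ids[dup & ave > 1] <- paste0(ids[dup & ave > 1], "_", ave[dup & ave > 1])
  ids
}

.annotateCds <- function(set, ids, geneName, species) {
  names(set) <- ids
  S4Vectors::mcols(set) <- S4Vectors::DataFrame(
    geneName = geneName,
    species = rep(species, length.out = length(set)))
  set
}

#' Convert RNA-alphabet sequences to DNA
#'
#' The quality filter works on the DNA alphabet and rejects U; run RNA
#' input through this first.
#'
#' @param x character vector or XStringSet
#' @return character vector with U/u mapped to T/t
#' @export
rnaToDna <- function(x) {
  if (is(x, "XStringSet")) x <- as.character(x)
  chartr("Uu", "Tt", x)
}

# ---- GenBank flat-file CDS extraction ----------------------------------

#' Extract CDS features from a GenBank flat file
#'
#' Minimal flat-file reader for local GenBank records: for every CDS
#' feature the \code{join}/\code{complement} location is resolved to the
#' spliced, strand-corrected nucleotide sequence taken from the ORIGIN
#' block.  The \code{/gene} qualifier, when present, is captured as the
#' gene name.  Malformed feature locations are skipped with a warning,
#' never fatal.  Multi-record files are supported.
#'
#' @param path GenBank flat-file path
#' @param species species tag; defaults to the record's LOCUS name
#' @return a BStringSet with \code{mcols} columns \code{geneName} and
#'   \code{species}; records in feature order
#' @export
readGenbankCds <- function(path, species = NULL) {
  if (!file.exists(path)) stop("cannot read GenBank file: ", path)
  lines <- readLines(path, warn = FALSE)
  recEnds <- grep("^//", lines)
  recStarts <- c(1L, utils::head(recEnds, -1L) + 1L)
  if (!length(recEnds)) { recStarts <- 1L; recEnds <- length(lines) }
  seqs <- character(0); ids <- character(0); genes <- character(0)
  spp <- character(0)
  for (r in seq_along(recStarts)) {
    rec <- lines[recStarts[r]:recEnds[r]]
    if (!length(rec) || !any(nzchar(rec))) next
    locus <- sub("^LOCUS\\s+(\\S+).*$", "\\1", grep("^LOCUS", rec, value = TRUE)[1])
    if (is.na(locus)) locus <- paste0("record", r)
    origin <- .genbankOrigin(rec)
    feats <- .genbankCdsFeatures(rec)
    k <- 0L
    for (ft in feats) {
      sq <- tryCatch(.resolveLocation(ft$location, origin),
                     error = function(e) {
                       warning("skipping CDS with malformed location in ",
                               locus, ": ", conditionMessage(e))
                       NULL
                     })
      if (is.null(sq)) next
      k <- k + 1L
      seqs <- c(seqs, sq)
      gname <- if (is.null(ft$gene)) "" else ft$gene
      ids <- c(ids, if (nzchar(gname)) paste0(locus, "_", gname)
               else paste0(locus, "_CDS", k))
      genes <- c(genes, gname)
      spp <- c(spp, if (is.null(species)) locus else species)
    }
  }
  set <- .annotateCds(Biostrings::BStringSet(seqs), .disambiguateIds(ids),
                      genes, "")
  S4Vectors::mcols(set)$species <- spp
  set
}

.genbankOrigin <- function(rec) {
  o <- grep("^ORIGIN", rec)
  if (!length(o)) stop("GenBank record has no ORIGIN block")
  body <- rec[(o[1] + 1L):length(rec)]
  body <- body[!grepl("^//", body)]
  toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
}

.genbankCdsFeatures <- function(rec) {
  f0 <- grep("^FEATURES", rec)
  oN <- grep("^ORIGIN", rec)
  if (!length(f0) || !length(oN)) return(list())
  feat <- rec[(f0[1] + 1L):(oN[1] - 1L)]
  keyLine <- grepl("^ {5}\\S", feat)
  starts <- which(keyLine)
  out <- list()
  for (i in seq_along(starts)) {
    key <- sub("^ {5}(\\S+).*$", "\\1", feat[starts[i]])
    if (key != "CDS") next
    end <- if (i < length(starts)) starts[i + 1L] - 1L else length(feat)
    block <- feat[starts[i]:end]
    # location spans the key line plus continuations until the first qualifier
    qual <- grep("^\\s+/", block)
    locEnd <- if (length(qual)) qual[1] - 1L else length(block)
    loc <- paste(gsub("\\s+", "", sub("^ {5}CDS", "", block[1:locEnd])),
                 collapse = "")
    gene <- NULL
    g <- grep("^\\s+/gene=", block, value = TRUE)
    if (length(g)) gene <- gsub("\"", "", sub("^\\s+/gene=", "", g[1]))
    out[[length(out) + 1L]] <- list(location = loc, gene = gene)
  }
  out
}

# Recursive resolver for GenBank location strings: a..b, single positions,
# join(...), order(...), complement(...); partial markers (< >) stripped.
.resolveLocation <- function(loc, origin) {
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    inner <- .stripOuterCall(loc, "complement")
    return(.revComp(.resolveLocation(inner, origin)))
  }
  if (grepl("^(join|order)\\(", loc)) {
    fun <- sub("\\(.*$", "", loc)
    inner <- .stripOuterCall(loc, fun)
    parts <- .splitTopLevel(inner)
    return(paste(vapply(parts, .resolveLocation, character(1), origin = origin),
                 collapse = ""))
  }
  if (grepl("^\\d+\\.\\.\\d+$", loc)) {
    ab <- as.integer(strsplit(loc, "\\.\\.")[[1]])
    if (ab[1] > ab[2] || ab[2] > nchar(origin))
      stop("interval out of range: ", loc)
    return(substr(origin, ab[1], ab[2]))
  }
  if (grepl("^\\d+$", loc)) {
    p <- as.integer(loc)
    if (p > nchar(origin)) stop("position out of range: ", loc)
    return(substr(origin, p, p))
  }
  stop("unsupported location syntax: ", loc)
}

.stripOuterCall <- function(loc, fun) {
  sub(paste0("^", fun, "\\("), "", sub("\\)$", "", loc))
}

.splitTopLevel <- function(s) {
  depth <- 0L; cuts <- integer(0)
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L); ends <- c(cuts - 1L, nchar(s))
  mapply(function(a, b) substr(s, a, b), starts, ends, USE.NAMES = FALSE)
}

.revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# ---- five-rule quality filter ------------------------------------------

#' Rule identifiers of the CDS quality filter, in checking order
#' @return character vector of rule ids
#' @export
filterRules <- function() {
  c("alphabet", "length_multiple_of_3", "start_codon",
    "stop_codon", "internal_stop", "min_length")
}

#' Apply the five-rule CDS quality filter
#'
#' A sequence is retained iff all of the following hold, checked in this
#' order with each rejection charged to the FIRST failing rule:
#' \enumerate{
#'   \item alphabet is exactly \{A,C,G,T\} (ambiguity codes fail here);
#'   \item length is a multiple of 3;
#'   \item it starts with ATG;
#'   \item it ends with TAA, TAG or TGA;
#'   \item no internal in-frame stop codon (premature termination);
#'   \item length is at least \code{minLength} nucleotides (300,
#'     inclusive).
#' }
#' Filtering is total (never errors) and idempotent.
#'
#' @param x BStringSet/DNAStringSet or named character vector of
#'   uppercase sequences
#' @param minLength minimum CDS length in nucleotides
#' @param code a [GeneticCode-class] supplying the stop codons
#' @return list with elements \code{retained} (a DNAStringSet carrying
#'   \code{geneName}/\code{species} metadata) and \code{report}
#'   (a [FilterReport-class])
#' @examples
#' x <- c(ok = paste0("ATG", strrep("GAT", 99), "TAA"), bad = "ATGNNNTAA")
#' res <- filterCds(x)
#' res$report
#' @export
filterCds <- function(x, minLength = 300L, code = geneticCode()) {
  meta <- NULL
  if (is(x, "XStringSet")) {
    meta <- S4Vectors::mcols(x)
    x <- as.character(x)
  }
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("gene_", seq_along(x))
  x <- toupper(x)
  stops <- stopCodons(code)
  failedRule <- vapply(x, .firstFailingRule, character(1),
                       minLength = minLength, stops = stops,
                       USE.NAMES = FALSE)
  keep <- failedRule == ""
  rejected <- data.frame(id = ids[!keep], rule = failedRule[!keep],
                         stringsAsFactors = FALSE)
  byRule <- setNames(integer(length(filterRules())), filterRules())
  if (nrow(rejected)) {
    tab <- table(factor(rejected$rule, levels = filterRules()))
    byRule[] <- as.integer(tab)
  }
  retained <- Biostrings::DNAStringSet(x[keep])
  names(retained) <- ids[keep]
  S4Vectors::mcols(retained) <-
    if (!is.null(meta)) meta[keep, , drop = FALSE]
    else S4Vectors::DataFrame(geneName = rep("", sum(keep)),
                              species = rep("", sum(keep)))
  report <- new("FilterReport",
                nInput = length(x), nRetained = sum(keep),
                rejectedByRule = byRule, rejectedIds = rejected)
  list(retained = retained, report = report)
}

.firstFailingRule <- function(s, minLength, stops) {
  if (grepl("[^ACGT]", s) || !nzchar(s)) return("alphabet")
  n <- nchar(s)
  if (n %% 3L != 0L) return("length_multiple_of_3")
  if (substr(s, 1L, 3L) != "ATG") return("start_codon")
  if (!substr(s, n - 2L, n) %in% stops) return("stop_codon")
  if (n > 3L) {
    internal <- substring(s, seq(1L, n - 5L, by = 3L), seq(3L, n - 3L, by = 3L))
    if (any(internal %in% stops)) return("internal_stop")
  }
  if (n < minLength) return("min_length")
  ""
}

#' Write a FilterReport's rejected ids to TSV
#' @param report a [FilterReport-class]
#' @param path output path; columns \code{id}, \code{rule_failed}
#' @return invisibly, the path
#' @export
writeFilterReport <- function(report, path) {
  stopifnot(is(report, "FilterReport"))
  tab <- report@rejectedIds
  names(tab) <- c("id", "rule_failed")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write coding sequences to FASTA
#' @param x XStringSet or named character vector
#' @param path output path
#' @return invisibly, the path
#' @export
writeCdsFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
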