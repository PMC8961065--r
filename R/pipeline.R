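.readCdsInput <- function(input, species = "") {
  if (is(input, "XStringSet")) return(input)
  if (is.character(input) && length(input) == 1L && file.exists(input)) {
    first <- readLines(input, n = 1L, warn = FALSE)
    if (grepl("^LOCUS", first)) return(readGenbankCds(input, species))
    return(readCdsFasta(input, species))
  }
  if (is.character(input)) return(Biostrings::BStringSet(toupper(input)))
  stop("input must be a file path, an XStringSet or a character vector")
}

.round2 <- function(x) round(x, 2)

#' Run the full single-genome codon-usage analysis
#'
#' Executes, in order: the five-rule CDS quality filter; codon counting;
#' positional GC composition (per gene and pooled); RSCU/RFSC with
#' preferred and high-frequency codon calls on the genome-aggregated
#' counts; per-gene ENc with GC3s and the expected-ENc curve value; PR2
#' coordinates (both the four-fold-family default and the all-codon
#' variant); the neutrality (GC12 on GC3) regression; correspondence
#' analysis of the gene x 59 RSCU matrix; per-gene SCUO and MILC (MILC
#' reference defaulting to the genome's own aggregate usage, optionally a
#' supplied pooled reference) and their Pearson correlation.  Genes with
#' undefined values in a given diagnostic are excluded from that summary
#' and reported, never silently imputed.
#'
#' @param input path to a FASTA or GenBank flat file, an XStringSet, or
#'   a character vector of sequences
#' @param species label used in summaries
#' @param outDir optional directory; when given, all result tables are
#'   written there as TSV (summary values at 2 dp, slopes at 4 dp)
#' @param milcReference optional named 64-codon count vector replacing
#'   the genome's own aggregate as the MILC expected distribution
#' @param pr2Mode family mode for the primary PR2 table
#' @param coaAxes number of correspondence-analysis axes to keep
#' @param code a [GeneticCode-class]
#' @return a result bundle (list) with elements \code{species},
#'   \code{report}, \code{codonTable}, \code{composition},
#'   \code{genomeComposition}, \code{indexTable}, \code{preferred},
#'   \code{highFrequency}, \code{geneDiagnostics}, \code{neutrality},
#'   \code{coa}, \code{expression}, \code{scuoMilc} and \code{summary}
#'   (one row mirroring the per-species summary table)
#' @export
runGenome <- function(input, species = "genome", outDir = NULL,
                      milcReference = NULL,
                      pr2Mode = c("fourfold", "all"),
                      coaAxes = 4L, code = geneticCode()) {
  pr2Mode <- match.arg(pr2Mode)
  raw <- .readCdsInput(input, species)
  flt <- filterCds(raw, code = code)
  if (length(flt$retained) == 0L)
    stop("no CDS passed the quality filter for ", species)
  ct <- codonTable(flt$retained, species = species)
  comp <- positionalComposition(ct, code)
  gcomp <- genomeComposition(ct, code)
  agg <- aggregateCounts(ct)
  idx <- codonIndexTable(agg, code)
  m <- countMatrix(ct)
  encRows <- lapply(seq_len(nrow(m)), function(i) {
    e <- suppressWarnings(encObserved(m[i, ], code))
    p4 <- pr2Point(m[i, ], code, familyMode = "fourfold")
    pa <- pr2Point(m[i, ], code, familyMode = "all")
    data.frame(gene = rownames(m)[i],
               gc3s = comp$gc3s[i],
               enc = e$enc,
               encExpected = if (is.na(comp$gc3s[i])) NA_real_
                             else encExpected(comp$gc3s[i]),
               pr2x_fourfold = p4$x, pr2y_fourfold = p4$y,
               pr2x_all = pa$x, pr2y_all = pa$y,
               stringsAsFactors = FALSE)
  })
  diag <- do.call(rbind, encRows)
  rownames(diag) <- NULL
  neut <- suppressWarnings(neutralityFit(comp))
  geneRscu <- rscuMatrix(ct, code)
  coa <- if (nrow(geneRscu) >= 3L) {
    suppressWarnings(coaRscu(geneRscu, axes = coaAxes))
  } else {
    warning("fewer than 3 genes; correspondence analysis skipped")
    new("CoaResult",
        rowCoords = matrix(0, nrow(geneRscu), 0,
                           dimnames = list(rownames(geneRscu), NULL)),
        colCoords = matrix(0, ncol(geneRscu), 0,
                           dimnames = list(colnames(geneRscu), NULL)),
        inertiaFraction = numeric(0), singularValues = numeric(0),
        axesKept = 0L)
  }
  expr <- expressionTable(ct, reference = milcReference, code = code)
  corr <- suppressWarnings(correlateScuoMilc(expr$scuo, expr$milc))
  summary <- data.frame(
    species = species,
    n_cds_input = flt$report@nInput,
    n_cds_retained = flt$report@nRetained,
    SCUO = mean(expr$scuo, na.rm = TRUE),
    MILC = mean(expr$milc, na.rm = TRUE),
    GC1 = 100 * gcomp$gc1, GC2 = 100 * gcomp$gc2,
    GC3 = 100 * gcomp$gc3, GC = 100 * gcomp$gc,
    ENc = mean(diag$enc, na.rm = TRUE),
    neutrality_slope = neut$slope,
    scuo_milc_r = corr$r,
    scuo_milc_p = corr$p,
    stringsAsFactors = FALSE)
  bundle <- list(species = species, report = flt$report, codonTable = ct,
                 composition = comp, genomeComposition = gcomp,
                 indexTable = idx,
                 preferred = preferredCodons(idx),
                 highFrequency = highFrequencyCodons(idx),
                 geneDiagnostics = diag, neutrality = neut, coa = coa,
                 expression = expr, scuoMilc = corr, summary = summary)
  if (!is.null(outDir)) .writeGenomeBundle(bundle, outDir)
  bundle
}

.writeGenomeBundle <- function(bundle, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  writeFilterReport(bundle$report, p("filter_report.tsv"))
  compOut <- cbind(gene = rownames(bundle$composition),
                   as.data.frame(lapply(bundle$composition, .round2)))
  write.table(compOut, p("composition.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeCodonIndexTable(bundle$indexTable, p("codon_index.tsv"))
  d <- bundle$geneDiagnostics
  write.table(data.frame(gene = d$gene, GC3s = .round2(d$gc3s),
                         ENc = .round2(d$enc),
                         ENc_expected = .round2(d$encExpected)),
              p("enc_gc3s.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = d$gene,
                         x_fourfold = .round2(d$pr2x_fourfold),
                         y_fourfold = .round2(d$pr2y_fourfold),
                         x_all = .round2(d$pr2x_all),
                         y_all = .round2(d$pr2y_all)),
              p("pr2.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = rownames(bundle$composition),
                         GC12 = .round2(bundle$composition$gc12),
                         GC3 = .round2(bundle$composition$gc3)),
              p("neutrality.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  neutSummary <- with(bundle$neutrality, data.frame(
    species = bundle$species, slope = round(slope, 4),
    intercept = round(intercept, 4), r = round(pearsonR, 3),
    p = round(pValue, 3), n_genes = nGenes))
  write.table(neutSummary, p("neutrality_fit.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (bundle$coa@axesKept > 0) {
    rc <- as.data.frame(bundle$coa@rowCoords)
    rc <- cbind(gene = rownames(rc), rc,
                GC = .round2(100 * bundle$composition[rownames(rc), "gc"]))
    write.table(rc, p("coa_genes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cc <- as.data.frame(bundle$coa@colCoords)
    write.table(cbind(codon = rownames(cc), cc), p("coa_codons.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(data.frame(axis = seq_along(bundle$coa@inertiaFraction),
                         inertia_fraction = bundle$coa@inertiaFraction),
              p("coa_inertia.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  ex <- bundle$expression
  write.table(data.frame(gene = ex$gene, L = ex$L, SCUO = .round2(ex$scuo),
                         MILC = .round2(ex$milc)),
              p("expression.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  s <- bundle$summary
  sOut <- data.frame(species = s$species,
                     n_cds_input = s$n_cds_input,
                     n_cds_retained = s$n_cds_retained,
                     SCUO = .round2(s$SCUO), MILC = .round2(s$MILC),
                     `GC1%` = .round2(s$GC1), `GC2%` = .round2(s$GC2),
                     `GC3%` = .round2(s$GC3), `GC%` = .round2(s$GC),
                     ENc = .round2(s$ENc),
                     neutrality_slope = round(s$neutrality_slope, 4),
                     r = round(s$scuo_milc_r, 3),
                     p = round(s$scuo_milc_p, 3),
                     check.names = FALSE)
  write.table(sOut, p("summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(outDir)
}

#' Run the multi-genome comparative codon-usage analysis
#'
#' Per-genome bundles (see [runGenome()]) plus the comparative surfaces:
#' the preferred-codon set shared by all genomes and its A/T-ending
#' count, the common high-frequency codon set, the species x 59 RSCU
#' matrix, the squared-Euclidean distance matrix, the between-groups
#' average-linkage dendrogram with its newick export, and the root
#' bipartition of the dendrogram.  Genomes whose single-genome run fails
#' are dropped from the comparative stage with a warning.
#'
#' @param inputs named list of inputs accepted by [runGenome()]; names
#'   are the species labels
#' @param outDir optional output directory (per-genome subdirectories
#'   plus comparative tables)
#' @param speciesRscuMode "aggregate" (RSCU of pooled genome counts,
#'   default) or "mean" (mean of per-gene RSCU vectors)
#' @param milcReference "self" (each genome against its own aggregate,
#'   default) or "pooled" (all genomes against the grand aggregate)
#' @param code a [GeneticCode-class]
#' @return list with \code{genomes} (bundles), \code{summary} (one row
#'   per species), \code{sharedPreferred}, \code{nSharedPreferredAT},
#'   \code{commonHF}, \code{rscuProfiles}, \code{distanceMatrix},
#'   \code{dendrogram}, \code{newick} and \code{rootPartition}
#' @export
runComparative <- function(inputs, outDir = NULL,
                           speciesRscuMode = c("aggregate", "mean"),
                           milcReference = c("self", "pooled"),
                           code = geneticCode()) {
  speciesRscuMode <- match.arg(speciesRscuMode)
  milcReference <- match.arg(milcReference)
  stopifnot(length(inputs) >= 2L)
  labels <- names(inputs)
  if (is.null(labels)) labels <- paste0("genome_", seq_along(inputs))
  pooledRef <- NULL
  if (milcReference == "pooled") {
    tables <- lapply(seq_along(inputs), function(i) {
      flt <- filterCds(.readCdsInput(inputs[[i]], labels[i]), code = code)
      codonTable(flt$retained, species = labels[i])
    })
    pooledRef <- aggregateCounts(do.call(rbind, lapply(tables, countMatrix)))
  }
  bundles <- list()
  for (i in seq_along(inputs)) {
    dir <- if (is.null(outDir)) NULL else file.path(outDir, labels[i])
    b <- tryCatch(
      runGenome(inputs[[i]], species = labels[i], outDir = dir,
                milcReference = pooledRef, code = code),
      error = function(e) {
        warning("genome '", labels[i], "' failed and is excluded: ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(b)) bundles[[labels[i]]] <- b
  }
  if (length(bundles) < 2L)
    stop("fewer than 2 genomes survived; no comparative analysis")
  tables <- lapply(bundles, `[[`, "codonTable")
  profiles <- rscuMatrix(tables, code, mode = speciesRscuMode)
  rownames(profiles) <- names(bundles)
  dm <- rscuDistanceMatrix(profiles)
  hc <- averageLinkage(dm)
  nwk <- toNewick(hc)
  prefSets <- lapply(bundles, `[[`, "preferred")
  shared <- Reduce(intersect, prefSets)
  hfSets <- lapply(bundles, `[[`, "highFrequency")
  commonHF <- Reduce(intersect, hfSets)
  summary <- do.call(rbind, lapply(bundles, `[[`, "summary"))
  rownames(summary) <- NULL
  out <- list(genomes = bundles, summary = summary,
              sharedPreferred = shared,
              nSharedPreferredAT = sum(endsInAT(shared)),
              commonHF = commonHF,
              rscuProfiles = profiles, distanceMatrix = dm,
              dendrogram = hc, newick = nwk,
              rootPartition = rootPartition(hc))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(cbind(species = rownames(profiles), round(profiles, 4)),
                file.path(outDir, "species_rscu_matrix.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cbind(species = rownames(dm), round(dm, 6)),
                file.path(outDir, "rscu_distance_matrix.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(nwk, file.path(outDir, "rscu_dendrogram.nwk"))
    sm <- summary
    num <- vapply(sm, is.numeric, logical(1))
    sm[num] <- lapply(sm[num], .round2)
    sm$neutrality_slope <- round(summary$neutrality_slope, 4)
    write.table(sm, file.path(outDir, "comparative_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(paste0("shared_preferred\t",
                        paste(sort(shared), collapse = ",")),
                 paste0("n_shared_preferred\t", length(shared)),
                 paste0("n_shared_preferred_AT_ending\t",
                        sum(endsInAT(shared))),
                 paste0("common_HF\t", paste(sort(commonHF), collapse = ",")),
                 paste0("n_common_HF\t", length(commonHF))),
               file.path(outDir, "comparative_codon_sets.tsv"))
  }
  out
}
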