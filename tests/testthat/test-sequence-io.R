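test_that("FASTA reading preserves order, uppercases and disambiguates ids", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">g1 some description [gene=psbA]", "atggataaataa",
               ">g2", "ATGAAATAA",
               ">g1 duplicate header token", "ATGCCCTAA"), path)
  x <- readCdsFasta(path, species = "toy")
  expect_length(x, 3L)
  expect_identical(as.character(x)[[1]], "ATGGATAAATAA")
  expect_false(anyDuplicated(names(x)) > 0)
  expect_identical(names(x)[1], "g1")
  expect_match(names(x)[3], "^g1_")
  expect_identical(S4Vectors::mcols(x)$geneName[1], "psbA")
  expect_identical(unique(S4Vectors::mcols(x)$species), "toy")
})

test_that("empty FASTA warns and returns an empty set", {
  path <- tempfile(fileext = ".fa")
  file.create(path)
  expect_warning(x <- readCdsFasta(path), "no FASTA records")
  expect_length(x, 0L)
  expect_error(readCdsFasta(tempfile()), "cannot read")
})

test_that("GenBank CDS extraction resolves join/complement locations", {
  path <- tempfile(fileext = ".gb")
  writeLines(toyGenbankLines(), path)
  x <- readGenbankCds(path)
  expect_length(x, 2L)
  origin <- toyGenbankOrigin()
  # forward single-exon CDS is a plain substring
  expect_identical(as.character(x)[[1]], substr(origin, 1, 21))
  # hand-spliced oracle for complement(join(5..13,30..38))
  spliced <- paste0(substr(origin, 5, 13), substr(origin, 30, 38))
  oracle <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(spliced)))
  expect_identical(as.character(x)[[2]], oracle)
  expect_identical(S4Vectors::mcols(x)$geneName, c("psbA", "toy2"))
})

test_that("GenBank records with no or malformed CDS degrade gracefully", {
  lines <- toyGenbankLines()
  noCds <- lines[!grepl("CDS|/gene", lines)]
  path <- tempfile(fileext = ".gb")
  writeLines(noCds, path)
  expect_length(readGenbankCds(path), 0L)
  bad <- sub("1\\.\\.21", "10..500", lines)   # interval beyond the origin
  writeLines(bad, path)
  expect_warning(x <- readGenbankCds(path), "malformed location")
  expect_length(x, 1L)                        # the other CDS survives
})

test_that("each filter rule charges exactly its own violation", {
  fx <- sevenSeqFixture()
  res <- filterCds(fx)
  rep <- res$report
  expect_identical(rep@nInput, 7L)
  expect_identical(rep@nRetained, 1L)
  expect_identical(names(res$retained), "s_pass")
  expect_identical(unname(rejectedByRule(rep)[filterRules()]),
                   rep(1L, 6L))
  charged <- setNames(rep@rejectedIds$rule, rep@rejectedIds$id)
  expect_identical(charged[["s_alphabet"]], "alphabet")
  expect_identical(charged[["s_mod3"]], "length_multiple_of_3")
  expect_identical(charged[["s_start"]], "start_codon")
  expect_identical(charged[["s_stop"]], "stop_codon")
  expect_identical(charged[["s_internal"]], "internal_stop")
  expect_identical(charged[["s_short"]], "min_length")
  # accounting invariant
  expect_identical(rep@nInput, rep@nRetained + sum(rejectedByRule(rep)))
})

test_that("filtering is total, idempotent and respects the length bound", {
  expect_silent(res <- filterCds(character(0)))
  expect_identical(res$report@nInput, 0L)
  # >= 300 is inclusive
  exactly300 <- paste0("ATG", strrep("GAT", 98), "TAA")
  expect_identical(nchar(exactly300), 300L)
  expect_length(filterCds(c(x = exactly300))$retained, 1L)
  g <- generateCdsSet(simulationConfig(nGenes = 8, seed = 4))
  mixed <- c(as.character(g$cds), sevenSeqFixture())
  first <- filterCds(mixed)
  again <- filterCds(as.character(first$retained))
  expect_identical(again$report@nRetained, first$report@nRetained)
  expect_identical(sum(rejectedByRule(again$report)), 0L)
})

test_that("retained CDS survive a FASTA round trip unchanged", {
  g <- generateCdsSet(simulationConfig(nGenes = 5, seed = 9))
  flt <- filterCds(g$cds)
  path <- tempfile(fileext = ".fa")
  writeCdsFasta(flt$retained, path)
  back <- readCdsFasta(path)
  expect_identical(as.character(back), as.character(flt$retained))
})

test_that("RNA input converts to DNA and then passes filtering", {
  rna <- "AUGGAUAAAUAA"
  expect_identical(filterCds(c(r = rna))$report@rejectedIds$rule, "alphabet")
  dna <- rnaToDna(rna)
  expect_identical(dna, "ATGGATAAATAA")
  expect_identical(filterCds(c(r = dna))$report@rejectedIds$rule, "min_length")
})
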