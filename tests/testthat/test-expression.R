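test_that("SCUO hits its endpoints exactly", {
  expect_equal(scuo(uniformFamilyCounts())$scuo, 0, tolerance = 1e-12)
  # one two-fold family used with a single codon
  cnt <- setNames(integer(64), allCodons())
  cnt[c("AAA", "AAG")] <- c(4L, 0L)
  expect_equal(scuo(cnt)$scuo, 1, tolerance = 1e-12)
  # single-codon usage in every observed multi-codon family
  one <- setNames(integer(64), allCodons())
  one[c("AAA", "GAT", "TTA", "GCT")] <- c(3L, 5L, 2L, 4L)
  expect_equal(scuo(one)$scuo, 1, tolerance = 1e-12)
})

test_that("SCUO is base-invariant and scale-invariant within families", {
  set.seed(12)
  cnt <- randomCountTable()
  res <- scuo(cnt)
  # independent oracle in log base 2
  code <- geneticCode()
  fams <- codonFamilies(code, minSize = 2)
  xi <- vapply(fams, function(cs) sum(cnt[cs]), numeric(1))
  Oi <- vapply(fams, function(cs) {
    x <- cnt[cs]; x <- x[x > 0]
    if (!length(x)) return(NA_real_)
    p <- x / sum(x)
    (log2(length(cs)) + sum(p * log2(p))) / log2(length(cs))
  }, numeric(1))
  oracle <- sum((xi / sum(xi)) * Oi, na.rm = TRUE)
  expect_equal(res$scuo, oracle, tolerance = 1e-12)
  expect_equal(scuo(cnt * 5L)$scuo, res$scuo, tolerance = 1e-12)
  none <- setNames(integer(64), allCodons()); none["ATG"] <- 3L
  expect_warning(r <- scuo(none), "undefined")
  expect_true(is.na(r$scuo))
})

test_that("MILC matches the one-family hand evaluation", {
  cnt <- setNames(integer(64), allCodons())
  cnt[c("TTT", "TTC")] <- c(3L, 1L)
  ref <- setNames(integer(64), allCodons())
  ref[c("TTT", "TTC")] <- c(10L, 10L)      # reference frequencies (0.5, 0.5)
  res <- milc(cnt, ref)
  M <- 2 * (3 * log(0.75 / 0.5) + 1 * log(0.25 / 0.5))
  expect_equal(res$milc, M / 4 - 1 / 4, tolerance = 1e-12)
  expect_equal(res$correction, 1 / 4)
  expect_identical(res$L, 4L)
  expect_false(res$pseudoApplied)
  # the coRdon-style baseline shifts the value up by exactly 0.5
  expect_equal(milc(cnt, ref, convention = "half")$milc,
               res$milc + 0.5, tolerance = 1e-12)
})

test_that("a reference-identical gene scores exactly -c", {
  set.seed(15)
  ref <- randomCountTable() + 1L          # strictly positive reference
  gene <- ref * 3L                        # identical family frequencies
  res <- milc(gene, ref)
  expect_equal(res$milc, -res$correction, tolerance = 1e-12)
  expect_gte(sum(res$perAa$Ma), -1e-12)   # divergences are non-negative
})

test_that("MILC of reference-sampled genes shrinks toward 0 with length", {
  code <- geneticCode()
  ref <- aggregateCounts(codonTable(
    generateCdsSet(simulationConfig(nGenes = 10, seed = 44))$cds))
  ref <- senseCounts(ref, code)
  q <- ref / sum(ref)
  set.seed(16)
  meanAbs <- vapply(c(100L, 1000L, 10000L), function(L) {
    mean(vapply(1:20, function(i) {
      gene <- setNames(as.integer(rmultinom(1, L, q)), allCodons())
      abs(milc(gene, ref, code)$milc)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanAbs) < 0))
  expect_lt(meanAbs[3], 0.05)
})

test_that("zero reference cells get the family pseudo-frequency and flag", {
  cnt <- setNames(integer(64), allCodons())
  cnt[c("TTT", "TTC")] <- c(2L, 2L)
  ref <- setNames(integer(64), allCodons())
  ref["TTT"] <- 10L                       # TTC unseen in the reference
  res <- milc(cnt, ref)
  expect_true(res$pseudoApplied)
  expect_true(is.finite(res$milc))
})

test_that("the SCUO-MILC correlation matches its closed form and is stable", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(correlateScuoMilc(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  set.seed(17)
  a <- runif(25); b <- runif(25)
  res <- correlateScuoMilc(a, b)
  rOracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$r, rOracle, tolerance = 1e-12)
  # symmetry and affine invariance
  expect_equal(correlateScuoMilc(b, a)$r, res$r, tolerance = 1e-12)
  expect_equal(correlateScuoMilc(3 * a - 1, b / 2 + 5)$r, res$r,
               tolerance = 1e-12)
  expect_warning(correlateScuoMilc(rep(0.2, 5), runif(5)), "zero variance")
})

test_that("expressionTable defaults to the genome's own reference", {
  g <- generateCdsSet(simulationConfig(nGenes = 8, seed = 18))
  ct <- codonTable(g$cds)
  tab <- expressionTable(ct)
  expect_identical(nrow(tab), 8L)
  expect_true(all(is.finite(tab$scuo)))
  expect_true(all(is.finite(tab$milc)))
  explicit <- expressionTable(ct, reference = aggregateCounts(ct))
  expect_equal(tab$milc, explicit$milc, tolerance = 1e-12)
})
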