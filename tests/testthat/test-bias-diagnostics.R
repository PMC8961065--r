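test_that("the expected-ENc curve takes its known values and symmetry", {
  expect_equal(encExpected(0.5), 60.5)
  expect_equal(encExpected(0), 31)
  expect_equal(encExpected(1), 32)
  s <- seq(0, 1, by = 0.01)
  expect_equal(encExpected(s) - encExpected(1 - s), 2 * s - 1)
  expect_equal(s[which.max(encExpected(s))], 0.5)
  expect_error(encExpected(1.2), "0, 1")
})

test_that("observed ENc approaches 61 under uniform synonymous usage", {
  code <- geneticCode()
  fams <- codonFamilies(code, minSize = 2)
  p <- setNames(numeric(64), allCodons())
  for (cs in fams) p[cs] <- (1 / length(fams)) / length(cs)
  set.seed(5)
  cnt <- setNames(as.integer(rmultinom(1, 10000, p)), allCodons())
  e <- encObserved(cnt, code)
  expect_lt(abs(e$enc - 61), 0.5)
  expect_identical(e$nMissingClasses, 0L)
})

test_that("ENc matches a hand evaluation of the class formula", {
  cnt <- setNames(integer(64), allCodons())
  cnt[c("TTT", "TTC")] <- c(2L, 2L)               # Phe: F = 1/3
  cnt[c("GGA", "GGC")] <- c(3L, 1L)               # Gly: F = 1/2
  cnt[c("ATT", "ATC", "ATA")] <- c(2L, 2L, 2L)    # Ile: F = 1/5
  cnt["TTA"] <- 6L                                # Leu: F = 1
  e <- encObserved(cnt)
  expect_equal(e$enc, 2 + 9 / (1 / 3) + 1 / (1 / 5) + 5 / (1 / 2) + 3 / 1)
  # single-class fixture: fallback fills the other classes with the mean
  lys <- setNames(integer(64), allCodons())
  lys["AAA"] <- 5L                                # F2 = 1
  expect_equal(encObserved(lys)$enc, 2 + 9 + 1 + 5 + 3)
})

test_that("ENc is clamped and undefined inputs warn", {
  none <- setNames(integer(64), allCodons())
  none["ATG"] <- 10L
  expect_warning(e <- encObserved(none), "undefined")
  expect_true(is.na(e$enc))
  g <- generateCdsSet(simulationConfig(nGenes = 5, seed = 77))
  for (i in 1:5) {
    enc <- encObserved(countMatrix(codonTable(g$cds))[i, ])$enc
    expect_gte(enc, 2); expect_lte(enc, 61)
  }
})

test_that("stronger within-family bias lowers ENc on paired simulations", {
  diffs <- vapply(1:20, function(s) {
    lo <- generateCdsSet(simulationConfig(nGenes = 8, biasTheta = 0.5, seed = s))
    hi <- generateCdsSet(simulationConfig(nGenes = 8, biasTheta = 2, seed = s))
    encObserved(aggregateCounts(codonTable(lo$cds)))$enc -
      encObserved(aggregateCounts(codonTable(hi$cds)))$enc
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gte(sum(diffs > 0), 18)
})

test_that("PR2 coordinates match hand division and the center case", {
  eq <- setNames(integer(64), allCodons())
  eq[c("GCA", "GCT", "GCG", "GCC")] <- 5L
  p <- pr2Point(eq)
  expect_equal(c(p$x, p$y), c(0.5, 0.5))
  cnt <- setNames(integer(64), allCodons())
  cnt[c("GCA", "GCT", "GCG", "GCC")] <- c(1L, 3L, 3L, 1L)
  p2 <- pr2Point(cnt)
  expect_equal(p2$x, 0.75)   # G3/(G3+C3) = 3/4
  expect_equal(p2$y, 0.25)   # A3/(A3+T3) = 1/4
  # swapping A<->T and G<->C within the family reflects about the center
  sw <- setNames(integer(64), allCodons())
  sw[c("GCT", "GCA", "GCC", "GCG")] <- c(1L, 3L, 3L, 1L)
  p3 <- pr2Point(sw)
  expect_equal(p3$x, 1 - p2$x)
  expect_equal(p3$y, 1 - p2$y)
})

test_that("PR2 family modes differ and zero denominators go missing", {
  cnt <- setNames(integer(64), allCodons())
  cnt[c("TTT", "TTC")] <- c(4L, 2L)     # 2-fold only
  p4 <- pr2Point(cnt, familyMode = "fourfold")
  expect_true(is.na(p4$x) && is.na(p4$y))
  pa <- pr2Point(cnt, familyMode = "all")
  expect_equal(pa$x, 0)                 # C only among G/C third positions
  expect_equal(pa$y, 0)                 # T only among A/T third positions
  gOnly <- setNames(integer(64), allCodons())
  gOnly["GGG"] <- 3L
  pg <- pr2Point(gOnly, familyMode = "all")
  expect_equal(pg$x, 1)
  expect_true(is.na(pg$y))              # zero A/T denominator goes missing
})

test_that("neutrality regression recovers an exact line and matches closed form", {
  gc3 <- seq(0.1, 0.4, length.out = 20)
  comp <- data.frame(gc3 = gc3, gc12 = 0.4 * gc3 + 0.2)
  fit <- neutralityFit(comp)
  expect_equal(fit$slope, 0.4, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.2, tolerance = 1e-12)
  expect_equal(fit$pearsonR, 1, tolerance = 1e-9)
  set.seed(14)
  comp2 <- data.frame(gc3 = runif(30, 0.1, 0.5),
                      gc12 = runif(30, 0.3, 0.6))
  fit2 <- neutralityFit(comp2)
  slopeOracle <- cov(comp2$gc3, comp2$gc12) / var(comp2$gc3)
  rOracle <- cov(comp2$gc3, comp2$gc12) / (sd(comp2$gc3) * sd(comp2$gc12))
  tOracle <- rOracle * sqrt(28 / (1 - rOracle^2))
  pOracle <- 2 * pt(-abs(tOracle), 28)
  expect_equal(fit2$slope, slopeOracle, tolerance = 1e-12)
  expect_equal(fit2$pearsonR, rOracle, tolerance = 1e-12)
  expect_equal(fit2$pValue, pOracle, tolerance = 1e-12)
  expect_identical(sign(fit2$slope), sign(fit2$pearsonR))
})

test_that("degenerate neutrality inputs are flagged, not fatal", {
  flat <- data.frame(gc3 = rep(0.3, 10), gc12 = runif(10))
  expect_warning(fit <- neutralityFit(flat), "zero variance")
  expect_true(is.na(fit$slope))
  expect_warning(neutralityFit(data.frame(gc3 = c(.1, .2), gc12 = c(.3, .4))),
                 "at least 3")
})
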