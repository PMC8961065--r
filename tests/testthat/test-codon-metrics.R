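leuFixture <- function() {
  cnt <- setNames(integer(64), allCodons())
  cnt[c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")] <- c(3L, 1L, 1L, 1L, 0L, 0L)
  cnt
}

test_that("RSCU and RFSC match hand evaluation on the leucine fixture", {
  tab <- codonIndexTable(leuFixture())
  leu <- tab[tab$aa == "L", ]
  expect_equal(leu["TTA", "rscu"], 3)
  expect_equal(leu["CTG", "rscu"], 0)
  expect_equal(leu["TTA", "rfsc"], 0.5)
  expect_equal(sum(leu$rscu), 6)
  expect_equal(sum(leu$rfsc), 1)
  # unobserved families are NA-flagged, not zero
  expect_true(all(is.na(tab$rscu[!tab$observed])))
})

test_that("uniform usage gives RSCU 1 everywhere and no preferred codon", {
  tab <- codonIndexTable(uniformFamilyCounts())
  multi <- tab[tab$ni >= 2 & tab$observed, ]
  expect_true(all(abs(multi$rscu - 1) < 1e-12))
  expect_length(preferredCodons(tab), 0L)
})

test_that("family sums and the rscu = rfsc * n identity hold on random tables", {
  set.seed(7)
  code <- geneticCode()
  for (rep in 1:25) {
    tab <- codonIndexTable(randomCountTable(), code)
    expect_equal(tab$rscu, tab$rfsc * tab$ni, tolerance = 1e-12)
    for (aa in unique(tab$aa)) {
      fam <- tab[tab$aa == aa, ]
      if (!fam$observed[1]) next
      expect_equal(sum(fam$rscu), fam$ni[1], tolerance = 1e-9)
      expect_equal(sum(fam$rfsc), 1, tolerance = 1e-9)
    }
  }
})

test_that("the index table is invariant to scaling all counts", {
  set.seed(8)
  cnt <- randomCountTable()
  a <- codonIndexTable(cnt)
  b <- codonIndexTable(cnt * 7L)
  expect_equal(a$rscu, b$rscu, tolerance = 1e-12)
  expect_equal(a$rfsc, b$rfsc, tolerance = 1e-12)
  expect_identical(a$preferred, b$preferred)
  expect_identical(a$highFrequency, b$highFrequency)
})

test_that("HF clauses fire as stated on two-fold and six-fold fixtures", {
  # 2-fold family at RFSC (0.7, 0.3): the 60% clause fires; the 1.5/n
  # clause does not (threshold 0.75)
  cnt <- setNames(integer(64), allCodons())
  cnt[c("TTT", "TTC")] <- c(7L, 3L)
  tab <- codonIndexTable(cnt)
  expect_true("TTT" %in% highFrequencyCodons(tab))
  expect_false("TTC" %in% highFrequencyCodons(tab))
  expect_false(0.7 > 1.5 / 2)
  # at (0.8, 0.2) both clauses fire
  cnt[c("TTT", "TTC")] <- c(8L, 2L)
  expect_true("TTT" %in% highFrequencyCodons(codonIndexTable(cnt)))
  # 6-fold: RFSC 0.5 > 1.5/6 = 0.25 even though 0.5 < 0.60
  tab6 <- codonIndexTable(leuFixture())
  expect_true("TTA" %in% highFrequencyCodons(tab6))
  expect_false(0.5 > 0.60)
})

test_that("stops screen as a TER family; Met/Trp never flag", {
  cnt <- setNames(integer(64), allCodons())
  cnt[c("TAA", "TAG", "TGA")] <- c(30L, 5L, 5L)
  cnt["ATG"] <- 100L; cnt["TGG"] <- 50L
  tab <- codonIndexTable(cnt)
  expect_true("TAA" %in% highFrequencyCodons(tab))
  expect_false(any(c("ATG", "TGG") %in% highFrequencyCodons(tab)))
  expect_false(any(c("ATG", "TGG", "TAA") %in% preferredCodons(tab)))
})

test_that("every family maximum above 60% lands in the HF set", {
  set.seed(9)
  for (rep in 1:10) {
    tab <- codonIndexTable(randomCountTable())
    for (aa in unique(tab$aa)) {
      fam <- tab[tab$aa == aa & tab$ni >= 2, ]
      if (!nrow(fam) || !fam$observed[1]) next
      top <- fam[which.max(fam$rfsc), ]
      if (top$rfsc > 0.60)
        expect_true(top$codon %in% highFrequencyCodons(tab))
    }
  }
})

test_that("preferred codons come from the leucine fixture as expected", {
  tab <- codonIndexTable(leuFixture())
  expect_identical(intersect(preferredCodons(tab), geneticCode()@families$L),
                   "TTA")
})

test_that("species RSCU matrices are deterministic and 59-dimensional", {
  g <- generateCdsSet(simulationConfig(nGenes = 6, seed = 13))
  ct <- codonTable(g$cds, "sp1")
  m1 <- rscuMatrix(list(sp1 = ct, sp2 = ct))
  expect_identical(dim(m1), c(2L, 59L))
  expect_equal(m1[1, ], m1[2, ])
  m2 <- rscuMatrix(list(sp1 = ct, sp2 = ct))
  expect_identical(m1, m2)
  # aggregate mode equals RSCU of pooled counts
  direct <- codonIndexTable(aggregateCounts(ct))
  expect_equal(unname(m1[1, ]),
               direct[analysisCodons(geneticCode()), "rscu"])
})

test_that("A/T-ending classification works on the DNA alphabet", {
  expect_identical(endsInAT(c("GCA", "GCT", "GCG", "GCC")),
                   c(TRUE, TRUE, FALSE, FALSE))
})
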