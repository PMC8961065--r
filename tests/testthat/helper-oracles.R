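# Fixtures and independent oracles shared across the suite.
# Everything here is built in code at test time; no binary fixtures.

# random 64-codon count table, with some zero cells
randomCountTable <- function(maxCount = 50L) {
  setNames(as.integer(sample(0:maxCount, 64, replace = TRUE)), allCodons())
}

# equal counts within every multi-codon family, zero elsewhere
uniformFamilyCounts <- function(code = geneticCode(), per = 10L) {
  cnt <- setNames(integer(64L), allCodons())
  for (cs in codonFamilies(code, minSize = 2L)) cnt[cs] <- per
  cnt
}

# Brute-force O(n^3) between-groups average linkage: clusters as label
# sets, merge the pair with minimal mean pairwise dissimilarity.
bruteAverageLinkage <- function(d) {
  clusters <- lapply(rownames(d), identity)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; bestv <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        v <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
        if (v < bestv) { bestv <- v; best <- c(j, i) }
      }
    }
    heights <- c(heights, bestv)
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, merges = merges)
}

# leaf-label sets created by each hclust merge, in merge order
hclustMergeSets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  mem <- function(x) if (x < 0) hc$labels[-x] else sets[[x]]
  for (k in seq_len(nrow(hc$merge)))
    sets[[k]] <- sort(c(mem(hc$merge[k, 1]), mem(hc$merge[k, 2])))
  sets
}

# Dense eigendecomposition oracle for correspondence analysis: the
# chi-square covariance route (eigen of t(S) S) instead of the SVD of S.
caEigenOracle <- function(m) {
  P <- m / sum(m)
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  ev <- eigen(t(S) %*% S, symmetric = TRUE)
  keep <- ev$values > 1e-12
  lambda <- ev$values[keep]
  V <- ev$vectors[, keep, drop = FALSE]
  G <- sweep(V, 1L, sqrt(cc), "/") %*% diag(sqrt(lambda), length(lambda))
  list(inertia = lambda / sum(lambda), colCoords = G, lambda = lambda)
}

# toy GenBank flat file: forward CDS plus complement(join(...)) CDS
toyGenbankLines <- function() {
  c("LOCUS       TOY1                 60 bp    DNA     linear   PLN 01-JAN-2020",
    "DEFINITION  synthetic toy record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             1..21",
    "                     /gene=\"psbA\"",
    "     CDS             complement(join(5..13,30..38))",
    "                     /gene=\"toy2\"",
    "ORIGIN",
    "        1 atggctaaag gttgacctaa acgtacgtac gtacgtacgt aaacctaggc atgcatgcaa",
    "//")
}

toyGenbankOrigin <- function() {
  toupper(gsub(" ", "",
    "atggctaaag gttgacctaa acgtacgtac gtacgtacgt aaacctaggc atgcatgcaa"))
}

# wrap a single long CDS into a minimal GenBank record
genbankFromCds <- function(seq, locus = "SYN1", gene = "geneX") {
  n <- nchar(seq)
  body <- substring(tolower(seq), seq(1, n, by = 60), pmin(seq(60, n + 59, by = 60), n))
  c(sprintf("LOCUS       %s               %d bp    DNA     linear   PLN 01-JAN-2020",
            locus, n),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    sprintf("     CDS             1..%d", n),
    sprintf("                     /gene=\"%s\"", gene),
    "ORIGIN",
    sprintf("%9d %s", seq(1, n, by = 60), body),
    "//")
}

# the seven-sequence filter fixture: sequences 1-6 each violate exactly
# one rule (in rule order), sequence 7 passes everything
sevenSeqFixture <- function() {
  ok <- paste0("ATG", strrep("GAT", 99), "TAA")      # 303 nt, clean
  c(s_alphabet = paste0("ATG", "NNN", strrep("GAT", 98), "TAA"),
    s_mod3     = paste0("ATG", strrep("GAT", 99), "TAAA"),
    s_start    = paste0("TTG", strrep("GAT", 99), "TAA"),
    s_stop     = paste0("ATG", strrep("GAT", 99), "GAT"),
    s_internal = paste0("ATG", strrep("GAT", 50), "TAA",
                        strrep("GAT", 48), "TAA"),
    s_short    = "ATGGATTAA",
    s_pass     = ok)
}
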