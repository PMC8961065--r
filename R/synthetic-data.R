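#' Configuration for the synthetic chloroplast-like CDS generator
#'
#' Defaults emulate a single chloroplast genome's filtered CDS
#' complement: 57 genes of 100-500 codons (always at least 300 nt), a
#' plant-protein-like amino-acid composition, a moderate within-family
#' tilt toward each family's A-ending (else T-ending) codon, and a
#' per-gene GC3 gradient tied to GC12 through a linear neutrality
#' structure, which lands pooled GC in the 30-45\% chloroplast-like
#' regime.
#'
#' @param nGenes number of genes (default 57)
#' @param lengthRange total gene length range in codons, start and stop
#'   included (default 100-500; the lower bound may not drop below 100
#'   so every gene clears the 300-nt filter)
#' @param aaComposition named probability vector over the 20 amino
#'   acids; NULL for the built-in plant-like default
#' @param biasTheta softmax tilt strength (>= 0) toward each family's
#'   designated A/T-ending codon; 0 gives uniform synonymous usage
#' @param gc3Targets either a numeric vector of per-gene GC3 targets; or
#'   a list with \code{slope}, \code{intercept}, \code{noiseSd} and
#'   \code{gc3Range} describing the neutrality structure: per-gene GC3
#'   drawn uniformly from \code{gc3Range} and GC12 set to
#'   \code{slope * GC3 + intercept + N(0, noiseSd)}; or NULL for no
#'   compositional targeting at all (pure \code{biasTheta} tilt, the
#'   setting in which \code{biasTheta = 0} means exactly uniform
#'   synonymous usage)
#' @param seed integer seed threaded through all sampling (the global
#'   RNG state is restored afterwards)
#' @return a list of class \code{SimulationConfig}
#' @export
simulationConfig <- function(nGenes = 57L,
                             lengthRange = c(100L, 500L),
                             aaComposition = NULL,
                             biasTheta = 1,
                             gc3Targets = list(slope = 0.15,
                                               intercept = 0.36,
                                               noiseSd = 0.02,
                                               gc3Range = c(0.14, 0.36)),
                             seed = 1L) {
  if (is.null(aaComposition)) aaComposition <- .defaultAaComposition()
  aaComposition <- aaComposition / sum(aaComposition)
  stopifnot(nGenes >= 1L, biasTheta >= 0,
            length(lengthRange) == 2L, lengthRange[1] <= lengthRange[2])
  if (lengthRange[1] < 100L)
    stop("lengthRange must start at >= 100 codons (>= 300 nt after filtering)")
  cfg <- list(nGenes = as.integer(nGenes),
              lengthRange = as.integer(lengthRange),
              aaComposition = aaComposition,
              biasTheta = biasTheta,
              gc3Targets = gc3Targets,
              seed = seed)
  class(cfg) <- "SimulationConfig"
  cfg
}

# Rough land-plant protein composition (percent scale; normalised on use).
.defaultAaComposition <- function() {
  c(A = 6, R = 5, N = 4.5, D = 4, C = 1.5, Q = 3.5, E = 5, G = 7, H = 2,
    I = 8, L = 10.5, K = 5, M = 2.5, F = 6.5, P = 4.5, S = 8, T = 5.5,
    W = 2, Y = 3.5, V = 6)
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Largest-remainder (quota) allocation of n items to probabilities p;
# deterministic, ties broken by index order.
.quota <- function(n, p) {
  if (n == 0L) return(integer(length(p)))
  p <- p / sum(p)
  x <- floor(n * p)
  r <- n * p - x
  need <- n - sum(x)
  if (need > 0) {
    # random tie-break: exact remainder ties are common (uniform p) and a
    # fixed-order break would hand the same codons the extra count in
    # every gene, biasing pooled usage
    idx <- order(-r, sample.int(length(p)))[seq_len(need)]
    x[idx] <- x[idx] + 1
  }
  as.integer(x)
}

# Designated preferred codon per family: the A-ending codon (first in
# codon-table order), else the T-ending one, else the first codon.
.preferredTarget <- function(cs) {
  third <- substr(cs, 3L, 3L)
  if (any(third == "A")) return(cs[third == "A"][1L])
  if (any(third == "T")) return(cs[third == "T"][1L])
  cs[1L]
}

# Within-family codon distribution under tilt exp(theta * preferred +
# phi * GC3); theta concentrates usage on the designated codon, phi
# steers third-position GC.
.famDist <- function(cs, theta, phi) {
  third <- substr(cs, 3L, 3L)
  gc3 <- as.numeric(third %in% c("G", "C"))
  pref <- as.numeric(cs == .preferredTarget(cs))
  w <- exp(theta * pref + phi * gc3)
  w / sum(w)
}

# Per-family constants for a fixed theta.  Because third-position GC is a
# 0/1 indicator, the tilted family normaliser is s0 + s1 * exp(phi) and
# the GC3 / GC12 expectations are closed forms in exp(phi); bisection
# over phi then costs O(#families) arithmetic per iteration.
.famSummaries <- function(fams, theta) {
  perFam <- lapply(fams, function(cs) {
    gc3 <- as.numeric(substr(cs, 3L, 3L) %in% c("G", "C"))
    g12c <- as.numeric(substr(cs, 1L, 1L) %in% c("G", "C")) +
            as.numeric(substr(cs, 2L, 2L) %in% c("G", "C"))
    wBase <- exp(theta * as.numeric(cs == .preferredTarget(cs)))
    list(cs = cs, gc3 = gc3, wBase = wBase,
         s0 = sum(wBase[gc3 == 0]), s1 = sum(wBase[gc3 == 1]),
         a0 = sum((wBase * g12c)[gc3 == 0]),
         a1 = sum((wBase * g12c)[gc3 == 1]))
  })
  list(perFam = perFam,
       s0 = vapply(perFam, `[[`, numeric(1), "s0"),
       s1 = vapply(perFam, `[[`, numeric(1), "s1"),
       a0 = vapply(perFam, `[[`, numeric(1), "a0"),
       a1 = vapply(perFam, `[[`, numeric(1), "a1"))
}

.subsetSummaries <- function(sums, aaNames) {
  list(perFam = sums$perFam[aaNames],
       s0 = sums$s0[aaNames], s1 = sums$s1[aaNames],
       a0 = sums$a0[aaNames], a1 = sums$a1[aaNames])
}

# Expected GC indicators per amino acid at tilt phi: e3 = third-position
# GC probability, g12 = expected GC count over positions 1 and 2 (0..2).
.aaExpectations <- function(sums, phi) {
  ephi <- exp(phi)
  z <- sums$s0 + sums$s1 * ephi
  list(e3 = sums$s1 * ephi / z, g12 = (sums$a0 + sums$a1 * ephi) / z)
}

.bisect <- function(f, target, lo = -30, hi = 30, iter = 40L) {
  flo <- f(lo); fhi <- f(hi)
  if (target <= flo) return(list(x = lo, clamped = TRUE))
  if (target >= fhi) return(list(x = hi, clamped = TRUE))
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
  }
  list(x = (lo + hi) / 2, clamped = FALSE)
}

.buildGene <- function(Ltot, gc3Target, gc12Target, theta, aaProbs, sums) {
  m <- Ltot - 2L                      # internal codons
  stopCodon <- sample(c("TAA", "TAG", "TGA"), 1L)
  fixed3 <- 1 + as.numeric(stopCodon == "TAG")   # ATG third is G
  fixed12 <- as.numeric(stopCodon == "TGA")      # TGA contributes one GC at pos2
  aaNames <- names(aaProbs)
  sums <- .subsetSummaries(sums, aaNames)
  targeting <- !is.na(gc3Target)
  pAa <- function(ps, ex) {
    w <- aaProbs * exp(ps * ex$g12 / 2)
    w / sum(w)
  }
  phi <- 0; psi <- 0; clamped <- FALSE
  if (targeting) {
    for (round in 1:2) {
      ex <- .aaExpectations(sums, phi)
      b <- .bisect(function(ps) {
        p <- pAa(ps, ex)
        (m * sum(p * ex$g12) + fixed12) / (2 * Ltot)
      }, gc12Target)
      psi <- b$x
      b <- .bisect(function(ph) {
        ex2 <- .aaExpectations(sums, ph)
        p <- pAa(psi, ex2)
        (m * sum(p * ex2$e3) + fixed3) / Ltot
      }, gc3Target)
      phi <- b$x
    }
  }
  ex <- .aaExpectations(sums, phi)
  w <- aaProbs * exp(psi * ex$g12 / 2)
  nAa <- .quota(m, w / sum(w))
  names(nAa) <- aaNames
  if (targeting) {
    # final GC3 calibration against the realised amino-acid counts
    b <- .bisect(function(ph) {
      ex2 <- .aaExpectations(sums, ph)
      (sum(nAa * ex2$e3) + fixed3) / Ltot
    }, gc3Target)
    phi <- b$x; clamped <- clamped || b$clamped
  }
  ephi <- exp(phi)
  famCounts <- list(); famDists <- list()
  for (aa in aaNames[nAa > 0]) {
    sm <- sums$perFam[[aa]]
    wFam <- sm$wBase * ephi^sm$gc3
    p <- wFam / sum(wFam)
    x <- .quota(nAa[[aa]], p)
    names(x) <- sm$cs
    famCounts[[aa]] <- x
    famDists[[aa]] <- setNames(p, sm$cs)
  }
  if (targeting) {
    # quota rounding accumulates across ~18 families; shift single counts
    # between third-position classes until the realised GC3 count matches
    # the target to the nearest codon
    targetCount <- round(gc3Target * Ltot) - fixed3
    famCounts <- .repairGc3(famCounts, famDists, targetCount)
  }
  seqStr <- .assembleGene(nAa, famCounts, stopCodon)
  list(seq = seqStr, famDists = famDists, clamped = clamped,
       stopCodon = stopCodon)
}

# Move single codon counts between AT-ending and GC-ending codons of the
# same family until the total third-position GC count equals targetCount
# (or no family can move further).  Donor/recipient codons are chosen by
# largest count / largest sampling probability, families by how far their
# allocation sits from its own expectation.
.repairGc3 <- function(famCounts, famDists, targetCount) {
  gcEnd <- function(cs) substr(cs, 3L, 3L) %in% c("G", "C")
  count3 <- function(fc) sum(unlist(lapply(fc, function(x) sum(x[gcEnd(names(x))]))))
  cur <- count3(famCounts)
  guard <- 0L
  while (cur != targetCount && guard < 5000L) {
    guard <- guard + 1L
    up <- cur < targetCount   # need more GC-ending codons
    moved <- FALSE
    resid <- vapply(names(famCounts), function(aa) {
      x <- famCounts[[aa]]
      g <- gcEnd(names(x))
      sum(x) * sum(famDists[[aa]][g]) - sum(x[g])
    }, numeric(1))
    ord <- names(famCounts)[order(resid, decreasing = up)]
    for (aa in ord) {
      x <- famCounts[[aa]]
      g <- gcEnd(names(x))
      if (!any(g) || all(g)) next
      from <- if (up) which(!g & x > 0) else which(g & x > 0)
      to <- if (up) which(g) else which(!g)
      if (!length(from)) next
      i <- from[which.max(x[from])]
      j <- to[which.max(famDists[[aa]][names(x)[to]])]
      x[i] <- x[i] - 1L; x[j] <- x[j] + 1L
      famCounts[[aa]] <- x
      cur <- cur + if (up) 1L else -1L
      moved <- TRUE
      break
    }
    if (!moved) break
  }
  famCounts
}

.assembleGene <- function(nAa, famCounts, stopCodon) {
  nAa <- nAa[nAa > 0]
  aaOrder <- sample(rep(names(nAa), nAa))
  codons <- character(length(aaOrder))
  for (aa in names(nAa)) {
    x <- famCounts[[aa]]
    codons[aaOrder == aa] <- sample(rep(names(x), x))
  }
  paste0("ATG", paste(codons, collapse = ""), stopCodon)
}

#' Generate a chloroplast-like synthetic CDS set
#'
#' Every gene starts with ATG, ends with a sampled canonical stop, and
#' contains no internal stop codon, so the whole set passes the quality
#' filter by construction.  Internal amino acids follow the configured
#' composition; within each synonymous family, codons follow a
#' softmax-tilted distribution combining the \code{biasTheta} preference
#' for the family's designated A/T-ending codon with a third-position
#' GC tilt whose strength is found by bisection so the gene's GC3 meets
#' its target; amino-acid composition is likewise tilted so GC12 meets
#' the neutrality-structure target.  Counts are allocated from these
#' distributions by largest-remainder quota and shuffled into the gene,
#' so realized GC3/GC12 match their targets up to rounding.  Infeasible
#' targets are clamped to the closest achievable value and flagged.
#'
#' @param config a [simulationConfig()]
#' @return list with \code{cds} (a DNAStringSet with gene metadata),
#'   \code{truth} (data.frame of per-gene targets and realizations) and
#'   \code{famDists} (per-gene within-family sampling distributions)
#' @examples
#' g <- generateCdsSet(simulationConfig(nGenes = 5, seed = 42))
#' filterCds(g$cds)$report
#' @export
generateCdsSet <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  code <- geneticCode()
  fams <- code@families
  sums <- .famSummaries(fams, config$biasTheta)
  .withSeed(config$seed, {
    n <- config$nGenes
    Ltot <- sample(seq(config$lengthRange[1], config$lengthRange[2]), n,
                   replace = TRUE)
    gt <- config$gc3Targets
    if (is.null(gt)) {
      gc3T <- rep(NA_real_, n)      # no compositional targeting
      gc12T <- rep(NA_real_, n)
    } else if (is.numeric(gt)) {
      gc3T <- rep_len(gt, n)
      gc12T <- rep_len(0.40, n)
    } else {
      gc3T <- runif(n, gt$gc3Range[1], gt$gc3Range[2])
      gc12T <- gt$slope * gc3T + gt$intercept + rnorm(n, 0, gt$noiseSd)
      gc12T <- pmin(pmax(gc12T, 0.05), 0.95)
    }
    genes <- vector("list", n)
    for (i in seq_len(n)) {
      genes[[i]] <- .buildGene(Ltot[i], gc3T[i], gc12T[i],
                               config$biasTheta, config$aaComposition, sums)
    }
    seqs <- vapply(genes, `[[`, character(1), "seq")
    ids <- sprintf("synth_g%03d", seq_len(n))
    names(seqs) <- ids
    cds <- Biostrings::DNAStringSet(seqs)
    S4Vectors::mcols(cds) <- S4Vectors::DataFrame(
      geneName = ids, species = rep("synthetic", n))
    comp <- positionalComposition(cds, code)
    truth <- data.frame(
      gene = ids, L = Ltot,
      targetGc3 = gc3T, realizedGc3 = comp$gc3,
      targetGc12 = gc12T, realizedGc12 = comp$gc12,
      clamped = vapply(genes, `[[`, logical(1), "clamped"),
      stringsAsFactors = FALSE)
    list(cds = cds, truth = truth,
         famDists = setNames(lapply(genes, `[[`, "famDists"), ids))
  })
}

#' Generate a pair of genomes at a controlled codon-usage divergence
#'
#' The first genome follows \code{config}.  The second keeps the first's
#' amino-acid usage but draws its within-family codon counts from
#' distributions interpolated between the first genome's realized
#' within-family usage and the uniform distribution:
#' \code{(1 - divergence) * observed + divergence * uniform}.  At
#' divergence 0 the two share codon usage (RSCU distance shrinks toward
#' 0 as genes grow); larger divergence yields larger expected
#' squared-Euclidean RSCU distance whenever the first genome is biased.
#'
#' @param config a [simulationConfig()] for the first genome
#' @param divergence interpolation factor in [0, 1]
#' @return list with \code{a}, \code{b} (each as from
#'   [generateCdsSet()]) and the family distributions used for the
#'   second genome
#' @export
generateReferenceGenomePair <- function(config, divergence) {
  stopifnot(divergence >= 0, divergence <= 1)
  a <- generateCdsSet(config)
  code <- geneticCode()
  fams <- code@families
  agg <- aggregateCounts(codonTable(a$cds))
  agg <- senseCounts(agg, code)
  distsB <- lapply(fams, function(cs) {
    tot <- sum(agg[cs])
    q <- if (tot > 0) agg[cs] / tot else rep(1 / length(cs), length(cs))
    p <- (1 - divergence) * q + divergence / length(cs)
    setNames(p / sum(p), cs)
  })
  aaTotals <- vapply(fams, function(cs) sum(agg[cs]), numeric(1))
  aaProbs <- aaTotals / sum(aaTotals)
  b <- .withSeed(if (is.null(config$seed)) NULL else config$seed + 1L, {
    n <- config$nGenes
    Ltot <- sample(seq(config$lengthRange[1], config$lengthRange[2]), n,
                   replace = TRUE)
    seqs <- character(n)
    for (i in seq_len(n)) {
      m <- Ltot[i] - 2L
      nAa <- .quota(m, aaProbs)
      names(nAa) <- names(aaProbs)
      famCounts <- lapply(names(nAa)[nAa > 0], function(aa) {
        x <- .quota(nAa[[aa]], distsB[[aa]])
        setNames(x, fams[[aa]])
      })
      names(famCounts) <- names(nAa)[nAa > 0]
      seqs[i] <- .assembleGene(nAa[nAa > 0], famCounts,
                               sample(c("TAA", "TAG", "TGA"), 1L))
    }
    ids <- sprintf("synthB_g%03d", seq_len(n))
    names(seqs) <- ids
    cds <- Biostrings::DNAStringSet(seqs)
    S4Vectors::mcols(cds) <- S4Vectors::DataFrame(
      geneName = ids, species = rep("synthetic_b", n))
    list(cds = cds)
  })
  list(a = a, b = b, famDistsB = distsB)
}

#' Write a generated CDS set with its ground-truth sidecar
#'
#' @param gen result of [generateCdsSet()]
#' @param fastaPath FASTA output path
#' @param truthPath TSV sidecar path (gene, L, target and realized GC3 /
#'   GC12, clamped flag)
#' @return invisibly, \code{fastaPath}
#' @export
writeCdsSet <- function(gen, fastaPath, truthPath = NULL) {
  writeCdsFasta(gen$cds, fastaPath)
  if (!is.null(truthPath))
    write.table(gen$truth, truthPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(fastaPath)
}
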