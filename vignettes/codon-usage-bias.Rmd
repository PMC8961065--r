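---
title: "Codon usage bias in chloroplast CDS sets: models, diagnostics and design notes"
author: "cubkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias in chloroplast CDS sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubkit)
```

## Scope and model

`cubkit` quantifies codon usage bias (CUB) in organellar protein-coding
gene sets — the setting where a genome contributes a few dozen CDS, GC
content sits well below 50%, and the question of interest is whether
synonymous codon choice is driven by mutation pressure, by selection, or
by both. The pipeline runs, per genome: CDS quality filtering, positional
GC composition, RSCU/RFSC with preferred- and high-frequency-codon
screens, ENc / PR2 / neutrality diagnostics, correspondence analysis of
gene-level RSCU vectors, and the SCUO and MILC expression proxies with
their correlation; across genomes it compares preferred/HF codon sets and
clusters species by squared Euclidean distance between RSCU profiles.

### Quality filter

A CDS is retained iff (in this order, each rejection charged to the first
failing rule): pure A/C/G/T alphabet; length a multiple of 3; ATG start;
TAA/TAG/TGA end; no internal in-frame stop; length at least 300 nt
(inclusive). The rule order is a package convention — the rules
themselves are standard but no canonical checking order exists, and
fixing one makes the per-rule rejection report deterministic. Ambiguity
codes are rejected rather than repaired, because every downstream
statistic needs exact base identities; `rnaToDna()` is provided for RNA
input, since U fails the DNA alphabet rule by design.

### Codon-level indices

With $x_{ij}$ the count of codon $j$ of amino acid $i$ and $n_i$ the
family size,
$$\mathrm{RSCU}_{ij} = \frac{x_{ij}}{\frac{1}{n_i}\sum_j x_{ij}}, \qquad
  \mathrm{RFSC}_{ij} = \frac{x_{ij}}{\sum_j x_{ij}},$$
so $\mathrm{RSCU} = \mathrm{RFSC}\times n_i$, RSCU sums to $n_i$ per
family and RFSC to 1. A codon is *preferred* when RSCU > 1 (within the
59-codon space: Met, Trp and stops excluded) and *high-frequency* when
RFSC exceeds 0.60 or $1.5/n_i$ — "1.5 times the family's average
frequency" is read as 1.5 times the uniform expectation $1/n_i$, the
standard form of this screen. Stop codons are excluded from preferred
calls but do compete as a single TER family in the HF screen, so a
dominant stop codon can be flagged. Ser, Leu and Arg are treated as
single six-fold families (the CodonW convention) rather than 2+4
subfamilies; this choice propagates to ENc's degeneracy classes, SCUO,
MILC and the 59-codon space, keeping all indices mutually consistent.

Genome-scope RSCU/RFSC are computed from counts aggregated over filtered
genes, not as means of per-gene values: aggregation never produces
undefined families and matches how genome-level heatmap values behave.
The mean-of-genes alternative is available (`rscuMatrix(mode = "mean")`)
for sensitivity checks.

### Composition conventions

GC1/GC2/GC3 are computed over the whole CDS including the terminal stop
codon (the whole-CDS convention; the stop contributes three positions
like any codon). GC3s and the third-position base fractions
(`t3s`..`g3s`) are restricted to codons of families with $n_i \ge 2$ —
the silent-capable sites — and are simple base fractions among those
positions. Genome-level values pool position tallies across genes
(codon-count weighted), which equals the composition of the concatenated
sequences exactly; an unweighted gene-mean mode exists because published
per-species tables do not always state which convention was used.

### Mutation-selection diagnostics

Observed ENc uses Wright's homozygosity estimator: per family with total
count $n > 1$, $\hat F = (n\sum_j p_j^2 - 1)/(n-1)$, averaged within
degeneracy classes $\{2, 3, 4, 6\}$ (9, 1, 5 and 3 families under the
conventions above), and
$\mathrm{ENc} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$,
clamped to $[2, 61]$. Families with $n \le 1$ are skipped ($\hat F$ is
undefined at $n = 1$); a missing three-fold class defaults to
$(\bar F_2 + \bar F_4)/2$ and any other missing class to the mean of the
available classes. The expected curve under pure compositional drift is
$\mathrm{ENc}(S) = 2 + S + 29/(S^2 + (1-S)^2)$ with $S$ = GC3s, maximal
(60.5) at $S = 0.5$.

PR2 coordinates are $G_3/(G_3+C_3)$ versus $A_3/(A_3+T_3)$. The default
restricts tallies to four-fold degenerate families, where every
third-position change is silent — the standard PR2-bias convention; the
all-codon variant is computed alongside because the two can differ
materially and published descriptions are often ambiguous about which
was used. The neutrality analysis regresses per-gene GC12 on GC3 by
ordinary least squares with a two-tailed t-based p-value on the Pearson
correlation; a slope near 1 indicates mutation pressure dominating, near
0 selection.

### Correspondence analysis

Gene-level RSCU vectors over the 59-codon space form a nonnegative table
analysed by classical (chi-square metric) correspondence analysis:
scale to grand total 1, standardized residuals
$(p_{ij} - r_i c_j)/\sqrt{r_i c_j}$, SVD, principal coordinates; axis
inertia fractions are $\sigma_k^2/\sum\sigma^2$ over all non-trivial
axes. Running CA on RSCU rather than raw counts removes amino-acid
composition effects before the decomposition, which is the point of the
RSCU representation; a raw-count mode is retained for comparison. Axis
sign is fixed by making each axis's largest-magnitude codon loading
positive — CA axes are otherwise sign-indeterminate and deterministic
output matters for regression testing. Four axes are kept by default.
Unobserved families yield missing RSCU entries, imputed as 0 (a gene
that never uses a family provides no contrast on it).

### Expression proxies

SCUO is the composition-weighted normalized entropy deficit
$\sum_i (x_i/\sum x_i)\,(\log n_i - H_i)/\log n_i$ over multi-codon
amino acids; it is 0 under uniform synonymous usage, 1 under
single-codon usage, and log-base invariant. MILC measures a gene's
divergence from a reference codon usage,
$$\mathrm{MILC} = \frac{\sum_a M_a}{L} - c, \qquad
  M_a = 2\sum_{j\in a} x_{aj}\ln\frac{f_{aj}}{g_{aj}}, \qquad
  c = \frac{\sum_a (n_a - 1)}{L},$$
with natural logarithms (MILC is not base-invariant, so the base is
fixed) and the reference defaulting to the gene's own genome aggregate
("average codon usage of the entire sample"); a pooled multi-genome
reference is available. Under this correction a reference-identical gene
scores exactly $-c$ and long reference-sampled genes score about 0. A
second convention subtracts an additional $-0.5$ from the correction,
shifting all values up by 0.5; `milc(convention = "half")` provides it
for comparability with tools using that baseline, and per-genome MILC
means around 0.55 in such tools correspond to about 0.05 here. Zero
reference frequencies for codons a gene uses are repaired by adding 0.5
to every reference count of the affected family — the smallest
intervention that keeps $M_a$ finite — and flagged.

Per-species summaries report unweighted means of per-gene SCUO and MILC
(one value per genome), plus the per-genome Pearson correlation between
the two with its two-tailed p-value.

### Clustering

Species profiles are the genome-aggregate RSCU vectors over the 59-codon
space; dissimilarity is the squared Euclidean distance (fed to the
linkage unmodified — squared distances are the documented input of the
SPSS "intergroup linkage" procedure this mirrors), and the hierarchy is
between-groups (unweighted average, UPGMA) linkage. Labels are sorted
lexicographically before clustering so the result is deterministic and
invariant to input order even under ties. Newick export places each
merge at half its linkage height (ultrametric convention); the root
bipartition is reported as two label sets, deliberately free of
taxonomic interpretation.

## The synthetic generator

`generateCdsSet()` emulates one chloroplast genome's filtered CDS
complement. Defaults, chosen once as the package's study conditions:

* 57 genes of 100–500 codons (start and stop included), so every gene
  clears the 300-nt filter — typical retained-CDS counts and lengths for
  a plastome;
* a land-plant-like amino-acid composition;
* `biasTheta = 1`: a softmax tilt toward one designated codon per family
  (the A-ending codon, else T-ending), reproducing the A/T-ending
  preference characteristic of plastid genomes. A tilt applied to *all*
  A/T-ending codons would be absorbed entirely by the GC3 calibration
  below (both act on the same third-position axis), so concentrating it
  on one codon per family keeps bias strength and composition targeting
  identifiable;
* a neutrality structure: per-gene GC3 targets uniform on [0.14, 0.36]
  and GC12 targets $0.15\,\mathrm{GC3} + 0.36 + N(0, 0.02)$, landing
  pooled GC in the 30–45% chloroplast-like regime with a weak
  mutation-pressure signal.

Within-family distributions combine the theta tilt with a third-position
GC tilt whose strength is found by bisection so the gene's expected GC3
equals its target (tolerance well below 0.01; infeasible targets — e.g.
below the floor pinned by Met/Trp/start codons — are clamped to the
closest achievable value and flagged). Amino-acid probabilities are
likewise exponentially tilted so expected GC12 meets its target, with
two alternating calibration rounds since six-fold families couple the
two tilts weakly.

Counts are then allocated by largest-remainder quota from these
distributions (ties broken randomly under the seed) and shuffled into
the gene, followed by a repair pass that shifts single counts between
third-position classes until realized GC3 matches its target to the
nearest codon. Quota allocation instead of i.i.d. multinomial draws is
deliberate: realized GC3/GC12 then match their targets up to rounding,
so the neutrality regression recovers the generating slope without the
attenuation that per-gene binomial sampling noise in the regressor would
cause. The residual per-seed spread of the recovered slope is the OLS
sampling error from the injected GC12 noise alone (about 0.04 at 57
genes and noise sd 0.02), which is why recovery checks assert the mean
over 20 seeds rather than every single seed.

All randomness flows through the single `seed` (the caller's RNG state
is saved and restored), so a fixed configuration reproduces its FASTA
byte for byte. `generateReferenceGenomePair()` derives a second genome
whose within-family distributions are interpolated between the first
genome's realized usage and uniform, giving a controlled codon-usage
divergence for comparative tests.

What the generator does *not* emulate: real chloroplast gene names and
functional classes, length-dependent amino-acid composition, inverted
repeat duplicates, strand-specific mutation asymmetry (PR2 structure),
or evolution along a tree — the "related" genomes are usage-level
perturbations, not descent with substitution. Passing tests therefore
demonstrate correctness of the statistics and internal consistency of
the pipeline on realistic-scale data, not biological conclusions about
any real taxon.

## Numerical choices and degenerate inputs

* Unobserved families: RSCU/RFSC stored as missing and flagged, never
  silently zero — except where a consumer defines an imputation (CA and
  distance matrices impute 0 with a warning).
* ENc with no estimable family at all is missing with a warning; values
  are clamped to $[2, 61]$.
* PR2 with a zero denominator yields a missing coordinate; summaries
  exclude-and-report rather than impute.
* Neutrality and correlation require 3 usable genes and nonzero
  variance; otherwise missing with a warning.
* CA on a constant table returns a zero-axis result with a warning;
  margins that are entirely zero are dropped.
* Tie-breaks: quota remainder ties are randomized under the seed
  (a fixed-order break would bias pooled usage); clustering ties are
  resolved by lexicographic label order.
* Table outputs are rounded only on write (2 decimals for summary
  percentages and indices, 4 for regression slopes); in-memory objects
  keep full precision.

## Problem sizes

Tests and the acceptance script run entirely on generated data: genomes
of 57 genes (100–500 codons), 20-replicate recovery loops, an 8-leaf
clustering oracle comparison over 20 draws, a 220-gene genome for the
uniform-usage limit, and a 5-genome comparative ladder. These sizes were
chosen to estimate each quantity comfortably inside its assertion
tolerance while keeping the whole suite fast on one CPU.

## Known limitations

* GenBank parsing covers the flat-file subset needed for CDS extraction
  (`join`/`order`/`complement` locations, `/gene` qualifiers); exotic
  location operators (e.g. external references) are skipped with a
  warning.
* The ML-phylogeny side of comparative work (alignment + tree inference)
  is out of scope; the dendrogram here is a codon-usage clustering, not
  a phylogeny.
* CodonW splits six-fold families differently in some of its outputs;
  numerical agreement with CodonW is expected for RSCU and ENc but not
  guaranteed for `*3s` fractions, where cubkit uses plain base fractions
  among silent-capable sites and documents the difference.

## A worked sketch

```{r example, eval = FALSE}
g <- generateCdsSet(simulationConfig(seed = 1))
bundle <- runGenome(g$cds, species = "demo", outDir = "demo_out")
bundle$summary
cmp <- runComparative(list(
  a = g$cds,
  b = generateReferenceGenomePair(simulationConfig(seed = 1), 0.2)$b$cds))
cmp$newick
```
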