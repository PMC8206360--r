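---
title: "Methods: ROH, genomic inbreeding and DAPC substructure in bovdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH, genomic inbreeding and DAPC substructure in bovdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovdiv)
```

## What the package models

`bovdiv` asks a population-genetic question about a single dairy cattle
breed: when cows of one breed are farmed and selected in different
production contexts — here, four PDO cheese consortia (Asiago, Grana
Padano, Parmigiano Reggiano, Trentingrana) and a drinkable-milk stream —
does their genome show measurable divergence? The package answers it with
three complementary instruments on dense autosomal SNP genotypes:

1. **Runs of homozygosity (ROH)** and the genomic inbreeding coefficient
   $F_{ROH}$, which quantify recent autozygosity *within* each subgroup;
2. a **K-means/BIC cluster-number scan** and **discriminant analysis of
   principal components (DAPC)**, which quantify substructure *between*
   subgroups;
3. **repeated stratified hold-out validation** of pairwise subgroup
   assignment, which turns "are they distinguishable?" into an
   out-of-sample accuracy with a replicate spread.

Because real herd-book genotypes are access-restricted, the package ships
a generative model of the whole design (`simulate_subpopulations()`,
`inject_autozygosity()`, `perturb()`) with complete ground truth, so every
stage is testable end to end.

## ROH detection

Detection follows the consecutive-SNP sliding-window method. A scanning
window of `window_snps = 40` SNPs slides one SNP at a time; a window is
*homozygous* if it holds at most one heterozygous and at most one missing
call. A SNP is in a candidate run if at least `window_hom_prop_min = 0.05`
of the windows overlapping it are homozygous; edge SNPs use only the
windows that exist. Candidate runs are maximal stretches of such SNPs,
split wherever consecutive SNPs are more than `max_gap_bp = 500` kb apart,
and each piece must hold at least 40 SNPs, span at least 1 Mb, and carry
at least one SNP per 50 kb of span. Run length is `end_bp - start_bp`,
the span between the first and last SNP — the convention that reproduces
published segment lengths from their coordinates (e.g. a segment at
10:34,352,857–36,318,731 is 1.97 Mb at two decimals.)

Three reading notes on this rule set:

* The heterozygote and missing allowances are independent: a window with
  one heterozygote *and* one missing call passes. The parameters are
  exposed so a stricter joint rule can be emulated by setting
  `max_missing_per_window = 0`.
* Heterozygous or missing SNPs whose window proportion passes remain
  inside the run and count toward its SNP tally — that is what a
  per-window allowance means for run content.
* Gap splitting happens *before* the SNP-count/length/density filters: a
  long gap interrupts the identity-by-descent evidence, so each side must
  qualify on its own.

The implementation uses cumulative sums; the test suite holds it to exact
equality with a brute-force oracle that enumerates every window
explicitly, across hundreds of randomized fixtures, and to full recovery
of tracts injected by the simulator.

$F_{ROH}$ is summed ROH length over the map-covered autosome length
$L = \sum_c (\text{last SNP}_c - \text{first SNP}_c)$. Using map-covered
length rather than a fixed 2.5 Gb constant keeps the coefficient
consistent across panels and makes the simulator's injected fraction and
the detector's estimate directly comparable. Per-chromosome values use the
same rule per chromosome, so the genome value is their length-weighted
mean.

ROH length classes are the conventional five (1–2, 2–4, 4–8, 8–16,
> 16 Mb), binned left-closed so a 2.00 Mb run falls in 2–4 Mb; the
published class labels overlap at integer boundaries and do not fix this,
so the left-closed rule is this package's resolution. Consensus regions
are intervals between consecutive SNP positions covered by the ROH of
*strictly more than* `support_min = 0.30` of a subgroup's members
("more than 30%"), snapped to SNP positions, with identical regions
merged across subgroups.

## Quality control

The variant/sample filters are the standard dense-panel set, applied in
the order sample call rate (> 10% missing removed), then per-variant call
rate (> 10%), minor allele frequency (< 1%), and the exact test of
Hardy–Weinberg equilibrium ($P < 10^{-4}$). Each removed variant is
tallied under the first criterion it fails, so the report telescopes. The
HWE test is the exact conditional test: given the observed allele counts,
the probability of every reachable heterozygote count follows a
hypergeometric-form distribution, and the two-sided p-value sums all
configurations no likelier than the observed one (with a `1e-9` relative
buffer against floating-point tie misordering). The suite checks it
against an independent log-factorial enumeration for every configuration
up to $n = 200$.

LD pruning slides a 50-SNP window by 5 SNPs; while any retained pair in
the window has $r^2 > 0.6$ (squared Pearson correlation of dosages over
pairwise-complete calls), the member of the first offending pair with the
smaller minor allele frequency is dropped, ties going to the later map
position — the documented behaviour of the standard pruning tool. An
undefined $r^2$ (a monomorphic column) carries no linkage signal and is
treated as no-LD. Pruning is deterministic and invariant to dosage
orientation. The ROH branch intentionally consumes the full post-QC
panel while only the structure branch uses the pruned subset: run density
matters for ROH, independence matters for PCA.

## Substructure: BIC scan and DAPC

Genotypes are mean-imputed, column-centred (no variance scaling, the
usual convention for biallelic dosages; scaling is available as a flag)
and decomposed by thin SVD. For each candidate cluster number
$K = 1..20$, Lloyd's K-means is run from 10 random initializations plus
one warm start that augments the best $K-1$ centres with the worst-fitted
point — this extra start makes the within-cluster sum of squares provably
non-increasing in $K$, which random restarts alone do not guarantee. The
score is the spherical-Gaussian profile BIC

$$\mathrm{BIC}(K) = n \log(\mathrm{WSS}_K / n) + K \log n,$$

with consecutive differences $\Delta \mathrm{BIC}$ read as strong
evidence when above 2.

**How many PCs to scan on.** This BIC is dimension-sensitive: splitting
an unstructured $d$-dimensional Gaussian reduces WSS by roughly a
$2/(\pi d)$ fraction, so a split of $n$ points profits whenever
$2n/(\pi d) > \log n$. Retaining too few components therefore over-splits
noise; the scan needs $d \gtrsim 2n/(\pi \log n)$ with generous
finite-sample margin (empirically ~3x, since K-means overfits sample
noise). `run_pipeline()` therefore scans on `max(50, 0.4 n)` components
by default — separate from the (usually smaller) DAPC retention count —
and `kmeans_bic_scan()` exposes the choice. At $n = 500$ with 100
retained PCs the simulator studies confirm `k_best = 1` on
undifferentiated data and `k_best = 5` on five subpopulations at
$F_{ST} \ge 0.05$, majorities over ten seeds.

DAPC fits linear discriminant axes in the retained-PC subspace by the
generalized eigenproblem on the Cholesky-whitened between-group matrix;
axes are scaled so the pooled within-group covariance is the identity in
discriminant space. Group priors are proportional to training group sizes
(equal under the balanced 200-per-subgroup design; sensible when the
simulator is unbalanced). Posteriors are Gaussian on discriminant-space
distances. A singular pooled covariance — possible when the retained-PC
count approaches the training count — is ridge-regularized with
$\varepsilon = 10^{-8}\,\mathrm{tr}(W)/d$ and a warning. New samples,
including raw genotype matrices, are always centred with the *model's*
variant means, never their own; the test suite checks the raw-genotype
path reproduces the score path exactly, and checks the whole fit against
an independent LDA implementation at full rank.

The retained-PC count for classification is chosen by repeated stratified
cross-validation (`xval_select_npcs()`): per replicate a 90:10 split
within groups, hold-out assignment success per candidate count, and
$\mathrm{RMSE} = \sqrt{\mathrm{mean}((1 - \mathrm{success})^2)}$;
the smallest count wins ties. Grid and replicate count are user choices
(defaults: 30 replicates) since no standard values exist.

Pairwise external validation repeats, ten times by default, a stratified
80:20 split of two subgroups, fits the PCA *on the training set only*,
trains a one-axis DAPC, and scores the untouched 20%. The mean and SD
over repetitions mirror the published heatmap convention. Whether to
re-select the PC count per pair or reuse one count is left to the caller
(`n_pcs` is per call); at the simulated scales 50 PCs on ~160 training
animals is comfortably below rank and the results are insensitive to
doubling it.

## The synthetic herd

`simulate_subpopulations()` draws ancestral allele frequencies uniformly
on [0.05, 0.95] and subgroup frequencies from the Balding–Nichols Beta
model with divergence parameter $F_{ST}$; genotypes are binomial given
the subgroup frequency, independently per SNP. The default design mirrors
the target study: 5 subgroups × 200 cows, 29 autosomes with realistic
length proportions (~2.49 Gb total), herd/sire/birth-year/panel metadata
for the cohort-selection filters, 1% missing calls and a 0.1%
hom-to-het error rate (the error mode that interrupts runs). The default
SNP count is a desk-scale 12,000; ~310 K is supported but slow in tests.
The default $F_{ST} = 0.02$ sits in the "same breed, mild substructure"
regime where pairwise hold-out assignment lands between chance and
ceiling; no divergence value is published for the real subgroups, so
analyses span a gradient instead of matching a point.

Autozygosity is injected per sample as non-overlapping tracts placed
uniformly, with exponential lengths above a 1 Mb floor (mean 2.11 Mb,
matching reported averages; the floor keeps every tract callable under
the 40-SNP/1 Mb rules, and the last tract is truncated so the realized
fraction hits the target). Within a tract each SNP becomes homozygous by
doubling an allele drawn from the subgroup frequency, preserving allele
frequencies inside runs.

What the simulator deliberately does **not** model: linkage
disequilibrium within subgroups (SNPs are independent given
frequencies), pedigree/sire family structure (sire metadata is
descriptive only), and selection signatures. Consequently, passing tests
demonstrate the correctness of the algorithms and their statistical
calibration under the stated model — not robustness to LD-induced
artefacts in real panels, where, e.g., the BIC scan is known to respond
to strong unpruned LD. That is precisely why the structure branch runs on
LD-pruned input.

## Numerical and reproducibility choices

* Coordinates are 1-based; intervals are closed; run and region length is
  `end - start` bp.
* Dosage counts the second (B) allele; every statistic used is invariant
  to orientation flips, which the suite asserts.
* All stochastic operations take an explicit seed, restore the caller's
  RNG state, and are bit-reproducible; `run_pipeline()` writes
  byte-identical artifacts on repeated runs with equal seeds.
* Problem sizes in the test suite are the package's chosen desk scale:
  ROH oracles run on 20 × 3,000-SNP fixtures; recovery studies use a
  1/12-scaled 29-autosome map (~208 Mb) at ~96 SNPs/Mb, where injected
  fractions {0, 0.05, 0.10, 0.20} are recovered within ±0.01; structure
  studies use 5 × 100 cows × 5,000 SNPs.
* The sliding-window method has a small known upward edge bias (runs can
  extend a few SNPs past a true autozygous tract, since boundary windows
  tolerate one heterozygote); at ≥ 50 SNPs/Mb this contributes well
  under 0.01 to $F_{ROH}$.

## A worked miniature

```{r example, eval = FALSE}
sim <- simulate_subpopulations(
  sim_params(n_pops = 5, n_per_pop = 40, n_snps = 8000, fst = 0.05,
             seed = 1))
res <- run_pipeline(sim$dataset, out_dir = tempfile(), seed = 1,
                    k_max = 10, n_pcs = 20)
glance(res$bic)        # k_best and minimum BIC
res$accuracy$overall   # DAPC reassignment accuracy
head(res$froh)         # per-cow genomic inbreeding
autoplot(res$bic)      # BIC curve
```

## Known limitations

* The spherical K-means BIC is a model-selection heuristic, not a test;
  its K is trustworthy only jointly with the ΔBIC evidence reading and,
  ideally, DAPC posterior structure.
* The exact-HWE tie rule uses a 1e-9 relative buffer; mathematically
  distinct configuration probabilities closer than that are treated as
  tied (beyond double precision's reliable ordering anyway).
* `ld_prune()` recomputes window correlation matrices naively; at several
  hundred thousand SNPs a compiled implementation would be preferable,
  but the desk scales used here complete in seconds.
* The consensus-region support is the minimum interval support across the
  merged region, a conservative choice the published convention does not
  pin down.
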