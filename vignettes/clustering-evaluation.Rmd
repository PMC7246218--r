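---
title: "Evaluating model-based clustering of microsatellite genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating model-based clustering of microsatellite genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Inferring the number of genetic clusters `K` from co-dominant marker data is
one of the most common — and least reliable — tasks in population genetics.
For a set of populations genotyped at a modest microsatellite panel (the
motivating design is ~90 domestic breeds, 25 diploids each, 15 loci), three
families of methods are in routine use:

* **Bayesian admixture clustering** (STRUCTURE-type MCMC), summarized by the
  estimated ln P(X|K) per replicate, the visual "plateau" rule for the
  smallest adequate K, and the Evanno ΔK statistic;
* **iterative reallocation clustering** (FLOCK-type), whose "plateau
  lengths" of identical re-run scores drive ad hoc stopping rules and a
  hierarchical partitioning;
* **discriminant analysis of principal components** (DAPC), with K chosen
  from the BIC curve of k-means solutions.

Each route carries its own failure modes: MCMC multimodality and
label-switching, ghost clusters under over-specified K, reallocation runs
that never co-locate, BIC curves without a sharp elbow.  `msatclust`
implements all three engines *plus the diagnostic machinery to decide
whether their answers deserve trust*, and a synthetic genotype generator so
every diagnostic can be exercised on data with a known truth.

## The synthetic world

`sim_scenario()` / `sample_frequencies()` / `sample_genotypes()` implement a
Balding–Nichols world: ancestral allele frequencies per locus are symmetric
Dirichlet(`ancestral_concentration`, default 1) over
`alleles_per_locus` (default 8, a typical microsatellite richness); each
population's frequencies are a Dirichlet draw
`Dirichlet(ancestral * (1 - theta) / theta)`, so `theta` is the expected
single-population F_ST.  A two-level variant (ancestral → group profile →
population) expresses nested breed-group structure.  Admixture acts at the
frequency level: an admixed population's frequency vector is a convex
combination of source populations' vectors — this is what F-statistics and
reallocation clustering "see", and it keeps the ghost/mode phenomenology
reproducible.  Within populations, genotypes deviate from Hardy–Weinberg
proportions by a per-population `fis`:
`P(het a≠b) = 2 p_a p_b (1 - f)`, `P(aa) = p_a^2 + f p_a (1 - p_a)`.
For negative `f` this distribution is infeasible whenever an allele is rarer
than `|f|/(1+|f|)`; the generator raises an invalid-parameter error rather
than silently renormalizing, which is why the built-in presets use only
non-negative `fis` even though heterozygote excess occurs in real breeds.

Three presets state the worlds the test-suite reasons about:

* `simple_k5` — five islands, `theta = 0.1`, no admixture, 2% missing data;
  the cleanly separable reference (5 × 25 × 15).
* `complex_breeds` — 30 populations in 5 groups (group-level drift
  0.05–0.20, within-group 0.004–0.05 plus one strongly drifted population
  so pairwise F_ST spans ≈ 0.004–0.45 with mean ≈ 0.11), and 13/30
  populations admixed across groups with only 60% weight on their own
  profile.
* `outgroup` — `complex_breeds` plus one `theta = 0.35` population, the
  analogue of a feral/wild outgroup whose mean differentiation against all
  others exceeds the within-domestic mean.

What a green test on these worlds does **not** establish: the generator has
no mutation model, no linkage, no pedigree structure, and frequency-level
admixture is a stand-in for individual-level gene flow; real data add all
of these plus genotyping error.

## The admixture engine

`run_replicate()` is a Gibbs sampler for the basic admixture model with the
*uncorrelated* allele-frequency prior: cluster frequencies
`P | Z ~ Dirichlet(lambda + counts)` (`lambda = 1`), individual ancestries
`Q | Z ~ Dirichlet(alpha + origin counts)`, allele-origin labels
`Z | (P, Q)` categorical, and a single scalar `alpha` shared by all
clusters updated by random-walk Metropolis (step 0.025) under a uniform
prior on (0, 10].  The correlated-frequency prior and the locality-informed
prior variant are deliberately out of scope: the diagnostics are
engine-agnostic, and `parse_structure_results()` ingests third-party runs
in a STRUCTURE-results-like dialect so they can be analyzed identically.

Two numerical facts matter and are documented here because they shape every
downstream diagnostic:

* **The reported ln P(X|K)** is `mean(lnL) - var(lnL)/2` over the
  post-burn-in sweeps, the estimator behind the usual P(K) values.  It is a
  harmonic-style approximation and carries a systematic *upward* bias
  relative to the exact marginal likelihood — on a small single-population
  fixture where the Dirichlet-multinomial marginal is available in closed
  form, the bias is 3–5% of |ln P|, far beyond the Monte-Carlo error.  The
  unit tests assert this measured relationship rather than exact agreement.
  The mean and variance are accumulated over *every* post-burn-in sweep;
  estimating them from a thinned trace makes the var/2 term the dominant
  source of between-replicate spread.
* **`alpha` needs its own burn-in.**  A random walk with step 0.025 takes
  roughly 2,000 sweeps to travel from the default start (1.0) to the
  posterior scale of a no-admixture world (~0.02).  Runs recorded before
  `alpha` equilibrates have inflated, heterogeneous lnL variances and
  therefore noisy ln P(K).  Desk-scale analyses here use burn-in ≥ 1,600;
  this is the package-level restatement of the standard "at least 10^4–10^5
  burn-in" guidance for the original tool.

`convergence_summary()` operationalizes the visual trace check: the drift
of the `alpha` and lnL traces between the last two windows, in pooled-SD
units, with a flag above 0.5.

## ΔK, the replicate-block protocol, modes and ghosts

`evanno_delta_k()` uses the mean-based form
`ΔK = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`, restricted to
the maximal contiguous prefix of the K grid (second differences are
undefined on an irregular grid); the per-replicate-second-difference
variant is exposed behind `per_replicate = TRUE` since both forms circulate
in the literature.  Ties break toward the smallest K.  `pritchard_kopt()`
operationalizes the visual plateau rule: the smallest K whose mean ln P is
within `tol_sd_multiple` (default 1) pooled SDs of the global maximum.

`block_analysis()` implements the replicate-block convergence protocol:
replicates in generation order are cut into blocks of 5; K_opt estimates
are recomputed per block and over accumulated block prefixes; the
accumulated trajectory is re-run under random permutations of the block
order.  The convergence verdict requires the accumulated K_opt[Evanno] to
be constant over the trailing `min(stability_window, floor(B/2))`
prefixes of the original *and every permuted* order.  The floor(B/2) guard
is a deliberate design choice: a one-block prefix estimates sd(ln P) from
5 replicates, which flips the ΔK argmax regardless of data quality or
chain length, and the full-scale protocol (B = 20) always judged
stability over trailing blocks, never over 1-block prefixes.  With B = 20
the rule reduces exactly to "the last `stability_window` blocks agree".

On the stated worlds the protocol behaves as the underlying phenomenon
dictates — and the direction of the effect is worth recording: with
well-burned-in chains, `simple_k5` (R = 20, K = 2–10) converges on
K_opt = 5, while `complex_breeds` does *not* converge: its per-block and
accumulated K_opt flip between 3 (the strong top-level group signal) and
6, including the characteristic "stable until the final block" pattern,
and randomized block orders disagree.  Notably the instability *grows*
with chain quality: poorly mixed chains fail to find the competing K = 6
structure at all and the protocol then converges, misleadingly, on K = 3.

`align_and_partition_modes()` aligns each replicate's Q to the
best-ln P replicate by greedy column matching (largest reference columns
first) and partitions replicates into modes as the connected components of
the graph whose edges join replicates with aligned similarity
`1 - ||Qi - Qj||_F / sqrt(2n)` at or above the threshold (default 0.9 — a
documented stand-in for dynamic threshold determination, which is not
reproducible from its description).  `detect_ghosts()` flags clusters whose
mean membership stays below 0.5 in every population and reports
`corrected_k = K - n_ghosts`; `clean_k_set()` returns the K values with a
single mode and zero ghosts; `evanno_on_major_modes()` recomputes ΔK on
major-mode replicates only.

## Reallocation clustering and its stopping rules

`flock_run()` performs, per run, a uniform random initial partition
followed by `n_reallocations` (default 20) rounds of: per-cluster allele
frequencies with add-one-per-allele smoothing (so unseen alleles never
yield -Inf), then reallocation of every individual to the cluster
maximizing its multilocus log10 genotype likelihood (HWE within cluster,
heterozygote factor 2, missing loci skipped).  The individual LLOD is the
log10 gap between best and second-best cluster; with the default threshold
0 the step is a pure argmax.  An emptied cluster is re-seeded with the
currently worst-fitting individual so k stays constant (the reference
tool's behavior is undocumented; plateau counting requires constant k).
Mean-LLOD scores are rounded to 2 decimals (the printed precision of the
reference tool) before plateau counting; `stopping_decision()` scans k
ascending and returns the first k whose plateau reaches `min_plateau`
(default 6) and strictly exceeds the plateau at k + 1.

`resolve_undecided()` implements the three-step resolution of an undecided
stopping condition: (1) outlier screen on the k = 2 per-population mean
LLOD map, operationalized as median ± 3 IQR (the multiplier is exposed);
outliers and non-outliers re-analyzed separately; (2) removal of
populations with < 80% single-cluster allocation as admixed, with verdict
"admixture-caused" if the remainder then decides and
"information-deficient" if not; (3) stepwise re-addition of the excluded
populations, logging which single additions re-break the decision.
`hierarchical_flock()` recurses the scan-decide-(resolve) cycle over each
decided cluster's member populations; the leaf count is K_opt[FLOCK].

A structural limitation measured on the `simple_k5` world and worth
knowing before trusting plateau-based stopping anywhere: the true 5-island
partition is a *fixed point* of the reallocation with perfect
self-assignment, yet uniform random initial partitions reach its basin only rarely at
theta = 0.1 with 15 loci (the test suite measures the hit rate — a few
percent of runs), so runs converge to many distinct local optima, no
rounded-LLOD plateau of length ≥ 6 forms at any k, and the hierarchy
terminates "information-deficient".  At theta = 0.2 every run co-locates
on the same solution and the hierarchy recovers all five islands.  The
stopping rules therefore measure *search reachability* as much as genetic
information content — which is precisely why their undecided verdicts need
the three-step resolution rather than being read as "no structure".

## DAPC

`genotype_pca()` encodes genotypes as per-allele dosages (0/1/2), imputes
missing entries with the locus-allele mean, centers, and keeps all
positive-eigenvalue components.  `bic_scan()` runs k-means (best of 10
starts) per K and scores `BIC(K) = n log(W_K / n) + K log(n)`.  The shape
of this curve depends on dimension: splitting a true cluster improves the
within-SS along only one of d axes, so for high-dimensional genotype
encodings the K log(n) penalty produces a minimum/elbow near the true K,
while in low dimension the curve can decrease indefinitely — the test
fixtures use d = 20 clouds for exactly this reason.  `select_k_ward()`
finds the "sharp change": successive BIC differences are split into two
groups by Ward's minimum-variance clustering and the selected K is the one
just after the last difference in the steep-decrease group; a flat or
rising curve returns the smallest K with a `no_structure` flag.
`fit_dapc()` is linear discriminant analysis on the first `retained_pcs`
(default 50) scores with posteriors restricted to `retained_das` (default
8) discriminant functions, reporting per-cluster reassignment proportions.

## Power and type-I simulation

`power_sim()` reimplements the classic generational drift scheme
(POWSIM-style), independent of the Dirichlet generator: each of `n_pops`
populations drifts from shared base frequencies by per-generation binomial
resampling of `2 Ne` allele copies over `t` generations
(`expected F_ST = 1 - (1 - 1/(2 Ne))^t`), then `n_per_pop` diploids are
sampled under HWE and global genic uniformity is tested.  The Fisher exact
test is evaluated per locus by Monte-Carlo sampling from the exact
conditional null given both table margins (i.i.d. Patefield tables rather
than a Markov chain — the same probability-ordering estimand, unbiased and
faster) and combined across loci by Fisher's method; the chi-square test
sums per-locus statistics and degrees of freedom.  `t = 0` gives the
type-I error.  At the reference breed-panel design (94 × 25 × 15, 8-allele
Dirichlet(1) frequencies) the Fisher route has 100% power at expected
F_ST = 0.0025 and both tests hold a type-I error of ~0.05, inside the
reported < 0.08 bound.  The (Ne, t) pairs behind the published expected
F_ST grid are not published; the defaults here
(Ne = 2000, t = 10 for F_ST = 0.0025) are a documented stand-in chosen to
keep drift loops short.

## Numerical and design choices not covered above

* Permutation p-values use the add-one rule `(1 + b)/(N + 1)`; the HWE
  Markov-chain p is a raw proportion (it may legitimately be 0, as in the
  reference implementation) and must be floored by the caller before
  Fisher combination — `combine_and_correct()` enforces this.
* Weir–Cockerham estimates combine variance components as
  ratio-of-sums over loci and alleles; per-locus sample sizes handle
  missingness; a population with fewer than 2 typed individuals at every
  locus is a named error.
* The Guo–Thompson-style HWE chain operates on an explicit vector of 2N
  allele slots: the uniform distribution over slot arrangements induces
  the Levene conditional distribution, so proposals (random slot swaps)
  are always accepted; diallelic cells go through full enumeration.
* Seeds: every stochastic stage derives an independent 31-bit stream from
  its inputs via a stable hash (`K`, replicate index, stage name), so
  K-scans are execution-order invariant and pipelines are byte-for-byte
  reproducible.
* The pipeline caches stage results under the output directory keyed by
  the global seed; diagnostics re-run from a cached K-scan cheaply.

## Known limitations

* The admixture engine implements the uncorrelated-frequency prior only;
  analyses that depend on the correlated prior's extra sensitivity must
  ingest external runs.
* ΔK on the `simple_k5` realization has a genuine secondary peak at K = 3
  (second differences 52 vs 80 ln-units with comparable replicate SDs);
  at R = 20 the Evanno argmax flips between 3 and 5 across seeds, while
  the plateau rule stays at 5.  This is a property of the estimator, not
  a bug, and it is exactly the fragility the block protocol is built to
  expose.
* Individual-level ancestry estimation from 15 microsatellites is
  information-limited: at pairwise F_ST 0.1 the Bayes-optimal posterior
  mean given the true frequencies already has a mean absolute error of
  ~0.12 against Beta(0.5, 0.5) truth; no sampler can beat that bound.
* Runtime envelope exercised by the tests: ≤ 30 populations, K ≤ 10,
  R ≤ 20, ≤ 4,000 sweeps.  Study-scale regimes (K to 90, R to 100,
  millions of iterations) are configurable but untested here.
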