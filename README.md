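# msatclust

Evaluation machinery for model-based population clustering of diploid
microsatellite genotypes.

Estimating the number of genetic clusters `K` in a set of populations — say,
~90 horse breeds genotyped at a 15-locus microsatellite panel, 25 animals
each — is routinely attempted with three method families that frequently
disagree: Bayesian admixture MCMC (STRUCTURE-type) summarized by ln P(X|K)
and the Evanno ΔK statistic; FLOCK-type iterative reallocation clustering
with plateau-based stopping rules; and DAPC with BIC-based K selection.
`msatclust` implements all three engines **and the diagnostics that decide
whether their answers deserve trust**:

* **I/O** — GenePop reader/writer (2- and 3-digit dialects), a STRUCTURE
  input writer, and a STRUCTURE-results-dialect reader/writer so external
  runs can be diagnosed identically to internal ones.
* **Synthetic genotypes** — a Balding–Nichols generator (`sim_scenario()`,
  `make_preset()`) with two-level drift (breed groups), frequency-level
  admixture, inbreeding and missingness; `theta` is the expected
  single-population F_ST.
* **Population statistics** — exact Hardy–Weinberg tests (Guo–Thompson
  Markov chain + diallelic enumeration), Fisher combination and Holm
  correction, Weir–Cockerham F_IS/F_ST with ratio-of-sums weighting,
  pairwise F_ST matrices, genic G-tests with genotype permutation, PCoA,
  and a POWSIM-style drift power / type-I simulation (`power_sim()`).
* **Admixture engine** — a compiled Gibbs sampler for the basic admixture
  model (`run_replicate()`, `run_kscan()`), reporting the
  `mean - var/2` estimator of ln P(X|K) and posterior mean memberships.
* **K diagnostics** — Evanno ΔK with peak ratios (`evanno_delta_k()`), the
  plateau rule (`pritchard_kopt()`), the replicate-block convergence
  protocol with randomized block orders (`block_analysis()`),
  label-switching mode alignment (`align_and_partition_modes()`),
  ghost-cluster detection (`detect_ghosts()`) and the clean-K set.
* **Reallocation clustering** — `flock_run()`, plateau tables and stopping
  rules, the three-step resolution of undecided stopping conditions, and
  hierarchical partitioning (`hierarchical_flock()`) whose leaf count is
  K_opt[FLOCK].
* **DAPC** — allele-dosage PCA, BIC scan over k-means solutions, Ward
  sharp-change K selection, and LDA posteriors (`dapc_engine()`).
* **Pipeline** — `run_pipeline()` / `subset_reanalysis()` orchestrate
  simulate → statistics → K-scan → diagnostics → reallocation → DAPC into
  cached, reproducible, comparable reports.

## Worked example

```r
library(msatclust)

# a stated world: five islands at F_ST 0.1, 25 diploids each, 15 loci
p <- make_preset("simple_k5")
g <- p$genotypes
wc_f_statistics(g)
#> Weir-Cockerham F-statistics: F_ST = 0.1040, F_IS = 0.0424

# replicated K-scan and the Evanno / plateau / block diagnostics
scan <- run_kscan(g, 2:10, r = 20,
                  sampler_config(burnin = 2200, iterations = 800, seed = 101))
evanno_delta_k(scan)
#> Evanno delta-K: K_opt = 5 (peak 6.58; ratio_12 = 1.65)
pritchard_kopt(scan)
#> [1] 5
block_analysis(scan, block_size = 5, n_permutations = 10, seed = 7)
#> block analysis: 4 blocks of 5; verdict: converged
#> accumulated K_opt[Evanno]: 5 5 5 5

# DAPC agrees
dapc_engine(g, k_max = 10, seed = 3)
#> DAPC: K_opt = 5
#>   mean reassignment: 1.000
```

The same protocol on the `complex_breeds` preset (30 admixed breed-group
populations) yields `verdict: not_converged` with the accumulated
K_opt[Evanno] flipping between 3 and 6 across replicate blocks and
randomized block orders — the diagnostic working as intended on a world
where ΔK has no stable answer.

The numbers above mean: the island world's differentiation is recovered at
its design value (F_ST ≈ 0.1); all three K-selection routes agree on the
five islands; and the replicate-block protocol certifies that the ΔK answer
is stable under both accumulation and reordering of replicates.

## Power / type-I simulation and `scripts/acceptance.R`

`scripts/acceptance.R` recomputes the two headline simulation quantities
from scratch with the installed package: the statistical power (in %) of
the global Fisher-exact genic-uniformity test under a 94-population ×
25-diploid × 15-locus drift design at expected F_ST = 0.0025, and the
type-I error (proportion) of the same battery at zero drift, taking the
maximum over the Fisher-exact and chi-square tests.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/clustering-evaluation.Rmd` documents the models, the stated
synthetic worlds, the estimator and burn-in behavior of the MCMC engine,
the convergence-verdict definition, the reallocation engine's
search-reachability limits, and all numerical defaults.
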