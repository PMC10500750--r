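---
title: "Quantifying overlap-driven overestimation bias in polygenic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying overlap-driven overestimation bias in polygenic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A polygenic risk score (PRS) is a weighted sum of risk-allele dosages,
$x_{PRS} = \sum_j \hat\beta_j \, g_j$, with weights estimated in a
*discovery* GWAS and performance measured in a *test* cohort. The headline
quantity is the additive gain of the PRS over a covariate-only model:

- Model I: $y = \beta\, x_{PRS}$
- Model II: $y = x_{co}^T a_{co} + x_{PC}^T b_{PC}$ (covariates + leading
  principal components, no PRS)
- Model III: Model II $+\ \beta\, x_{PRS}$

$\Delta AUC = AUC_{III} - AUC_{II}$ (binary traits, DeLong test for paired
AUCs) and $\Delta R^2 = R^2_{III} - R^2_{II}$ (Nagelkerke pseudo-$R^2$ for
binary traits; adjusted $R^2$ with the extra-sum-of-squares F test for
quantitative traits).

These gains are only honest if discovery and test subjects are independent.
When the same individuals — or their close relatives — appear in both
cohorts, the per-SNP weights partially memorize the test subjects and the
gain is overestimated. Large consortium datasets make such overlap common
and hard to detect when only summary statistics are released. This package
provides a controlled laboratory for the phenomenon: a cohort simulator
with dial-in overlap, the full clumping+thresholding PRS pipeline, a
PLINK-style identity-by-descent screen to find and remove overlapping
subjects, and orchestrated experiments that measure the inflation and its
repair.

## The cohort simulator

`simulate_genotypes()` draws biallelic dosages under Hardy–Weinberg
equilibrium with per-variant counted-allele frequencies uniform in
`maf_range` (default 1%–50%). Linkage disequilibrium is induced by an
exchangeable-correlation Gaussian copula: within each block of `block_size`
consecutive variants a latent normal with correlation `rho` is thresholded
at the HWE genotype quantiles; blocks are independent. This is the simplest
LD model that makes clumping non-trivial; real LD maps, population
structure, admixture, genotyping error and the X chromosome are out of
scope. Variants are laid out on synthetic chromosomes of 1000 variants at
5 kb spacing, so the default ±1 Mb clump window spans ~400 variants.

`assign_effects()` samples `n_causal` variants uniformly and draws their
effects on *standardized* genotypes from $N(0, h^2/n_{causal})$, so the
genetic variance equals $h^2$ in expectation regardless of the MAF
spectrum. The liability is $l = g + e$, $e \sim N(0, 1-h^2)$.
`simulate_phenotype()` emits a binary trait by thresholding the liability
at the quantile matching prevalence $K$, or the liability itself as a
quantitative trait. Reference points used throughout: $h^2 = 0.497$
(height-like quantitative trait), $h^2 = 0.147$ (hypertension-like binary
trait), and a default case fraction $K = 0.314$ typical of a large
case-enriched discovery cohort.

Nuisance covariates (`age`, `sex`, `center`) are generated independently of
genotype with configurable standardized liability coefficients, zero by
default — so principal components and covariates are pure nuisance and any
gain must come from the genotypes. With nonzero coefficients the threshold
is scaled by the theoretical standard deviation of the total liability so
the realized prevalence still tracks $K$.

Overlap is *verbatim copy*: `build_cohorts()` and `inject_overlap()` place
the identical subject (same ID, genotype, phenotype) in both cohorts,
matching the situation of one person sequenced by two initiatives.
Cross-platform genotype discordance for shared subjects is not modeled.
`spawn_relative()` produces duplicates, parent–offspring pairs (one allele
transmitted, one drawn from the population) and full siblings (two
reconstructed parents, Mendelian re-draw), giving the standard
IBD-state distributions.

All randomness flows from the config seed through `derive_seed(seed,
counter)`; identical configuration implies bit-identical cohorts.

## Discovery GWAS and PCs

`run_gwas()` fits `phenotype ~ dosage + covariates` per variant: logistic
regression by iteratively reweighted least squares (coefficient-change
tolerance 1e-8, at most 25 iterations, separation flagged non-converged)
for binary traits, exact least squares for quantitative traits. Wald betas,
SEs and two-sided normal p-values are reported; monomorphic variants get
$\beta = 0, p = 1$ and a flag. The logistic scan is a compiled
(RcppArmadillo) kernel warm-started from the covariate-only fit; the
quantitative scan residualizes phenotype and dosages on the covariates
(Frisch–Waugh) and recovers the exact full-model slope and SE. Both are
verified against `stats::glm`/`stats::lm` in the tests.

`compute_pcs()` returns orthonormal principal-component scores of the
standardized dosage matrix with a deterministic sign convention (the
largest-magnitude loading of each component is positive). The evaluation
models use 20 leading PCs by default.

## Clumping + thresholding PRS

`filter_sumstats()` applies MAF ≥ 1%, $P < 0.5$ and interval exclusions
(1-based, inclusive ends — the analog of removing everything within 1 Mb
of a dominant locus such as the APOE region in Alzheimer's analyses).
`clump()` is the greedy PLINK-style algorithm: scan variants by ascending
p; each becomes an index SNP and prunes all not-yet-kept variants on the
same chromosome within ±1 Mb whose dosage $r^2$ with it reaches 0.1.
Ties are broken `(p, chrom, pos, variant_id)` lexicographically so results
are deterministic. An independent brute-force oracle (full rescan after
every index selection) confirms exact set equality on random instances.
The LD panel defaults to the discovery panel (raw-genotype PRS); a
test-panel LD reference can be passed for summary-statistics-only
workflows.

`prs_score()` matches alleles explicitly: direct match uses the dosage,
counted/other swap reflects it ($2-d$), strand-ambiguous SNPs (A/T, C/G)
are dropped, missing dosages are imputed as twice the effect-allele
frequency (PLINK `--score` mean imputation). Scores are linear in the
betas by construction. `select_top(k)` implements the "lowest P first"
SNP-count sweeps.

## Duplicate and relative detection (PI_HAT)

`estimate_pi_hat()` implements the method-of-moments IBD estimator behind
PLINK `--genome`: per-locus IBS-state probabilities given IBD state under
HWE, summed over loci, solved for $P(IBD=0/1/2)$, clamped to $[0,1]$ and
renormalized; $\hat\pi = P(IBD{=}2) + \tfrac12 P(IBD{=}1)$. All cross-panel
pairs are computed via indicator-matrix crossproducts (BLAS-bound), so an
800×3000 all-pairs scan over a few thousand loci takes seconds.

Numerical caveats, documented because they matter in practice:

- Allele frequencies are plug-in estimates pooled over both panels (or
  supplied externally). Frequencies estimated from fewer than a few dozen
  samples visibly distort the moments; use a large frequency source.
- The estimator assumes independent loci. Strong LD inflates the null
  spread of $\hat\pi$ (it does for PLINK too); compute on LD-pruned or
  subsampled loci (`max_loci`). Duplicates ($\hat\pi = 1$) and first-degree
  relatives ($\hat\pi \approx 0.5$) separate cleanly from unrelated pairs
  from ~2000 informative loci.

`prune_overlap()` removes every test subject whose maximum cross-cohort
$\hat\pi$ reaches the cutoff (0.9 catches duplicates; ~0.4 additionally
sweeps first-degree relatives) and reports the removed pairs. The cutoff is
a required argument: no silent default is applied.

## Evaluation metrics

`evaluate()` fits Models II and III on the intersection of samples and
reports the gain. The DeLong test uses the midrank structural-component
formulation; it agrees with `pROC::roc.test` to machine precision (tested)
and returns $p = 1$ by convention when the variance of the AUC difference
is zero (e.g. identical score vectors). Nagelkerke $R^2$ uses the
intercept-only model as the baseline for both $R^2_{II}$ and $R^2_{III}$
(matching the commonly used `fmsb` implementation), so $\Delta R^2$ is
their difference. For quantitative traits the headline $\Delta R^2$ is the
difference of adjusted $R^2$ and the p-value comes from the
extra-sum-of-squares F test (equal to the squared t of the PRS coefficient
when one term is added); the unadjusted $R^2$s are also reported. A
constant or collinear PRS column is dropped with a warning so the
degenerate case evaluates to exactly zero gain. `stratified_kfold()`
provides covariate-balanced 9:1 cross-validation splits (continuous
columns binned into quintiles; strata smaller than k merged with a
warning).

## The experiments

All experiment drivers take a `sim_config`, derive one seed per grid cell
from the master seed (recorded in the output), and summarize per grid point
as mean ± sd over replicates; $-\log_{10} p$ is floored at $10^{-300}$.
Desk-scale default dimensions — 5000 variants in blocks of 20 at
$\rho = 0.6$, 200 causal variants, discovery 3000, test 800 — were chosen
once so a full contamination sweep runs in minutes on one CPU; the
acceptance checks state the exact sizes they use.

- `contamination_experiment()`: overlap fraction 0 → 1 by 0.1; one
  GWAS+clump per replicate, then `inject_overlap()` and re-evaluation per
  fraction. A single-locus reference model (dosage of the strongest causal
  variant, the stand-in for a known major risk allele) is evaluated
  alongside: its gain does not depend on overlap, confirming that the test
  set keeps its character while the PRS inflates.
- `prune_repair_experiment()`: clean / 30%-contaminated / PI_HAT-pruned
  arms of the same replicate; pruning at 0.9 returns the gain to the clean
  arm within sampling error.
- `scale_experiment()`: fixed test set, discovery resampled at each size
  (default 1k/3k/9k — a desk-scale homolog of 9k/60k/300k cohort tiers);
  reports the fitted slope of the mean gain per sample and per 3k samples.
- `snp_count_sweep()`: gain versus top-k SNPs of one clumped selection;
  k = 0 collapses to zero gain, and the curve flattens once the causal
  variants are captured.
- `power_curve()`: fraction of replicates with DeLong $p < \alpha$
  (default 0.01) per test size; "sufficient power" is operationalized as
  0.8, a deliberate package choice.
- `ratio_experiment()`: discovery case count held fixed while the
  control:case ratio varies (default 0.33/1/3) against a fixed test set;
  more controls at fixed cases means higher gain.

## What passing tests do and do not show

The simulator reproduces the *mechanisms* — leakage through shared
subjects, the scale effect of discovery size, detectability of duplicates —
under exchangeable-block LD and a fully additive liability. Passing tests
therefore validate the pipeline's logic and calibration, not any real
cohort's effect sizes: real data add LD structure, platform differences
between cohorts sequenced twice, phenotype misclassification and
population stratification, all of which are out of scope here. The
acceptance checks are property-based (monotonicity, calibration, recovery)
rather than numeric reproductions of cohort-specific results.

## Known limitations

- No population structure: PCs are pure nuisance here, so these runs cannot
  measure stratification-driven inflation.
- Integer dosages only; imputed (fractional) dosages are not modeled.
- The IBD screen is all-pairs $O(n_a n_b M)$; use `max_loci` for large
  cohort pairs.
- Overlapping subjects are bit-identical across cohorts; cross-platform
  genotype discordance would lower PI_HAT slightly below 1 in real data,
  which a 0.9 cutoff still catches.
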