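---
title: "Methods: two-stage hybrid genomic prediction in hybridgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage hybrid genomic prediction in hybridgp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, the synthetic-data generator, the
numerical choices and the known limitations of `hybridgp`. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Hybrid genotype coding

Hybrids are single crosses of (nominally) inbred parents. The additive
dosage of a hybrid at a marker is the mean of its two parents' 0–2 dosages —
the expected dosage of the cross, and the unique coding that reproduces the
0/1/0.5/1.5 class structure of inbred-derived F1s. The dominance content is
a heterozygosity indicator: 1 when the parents are opposite homozygotes, 0
when they share a homozygous class, and *missing* for the intermediate
additive values 0.5 and 1.5 that arise when exactly one parent is
heterozygous (residual heterozygosity in incompletely inbred lines). Missing
dominance (and additive) entries are mean-imputed per marker before kernels
are built.

Marker QC removes markers with minor allele frequency below 1% or
missingness above 30% (defaults; both are arguments of `filter_markers()`).
A marker failing both rules is attributed to the MAF rule, which is applied
first, so the QC report's counts always sum to the input count. QC is
applied to the *hybrid* additive matrix by default, since that matrix feeds
the analysis; filtering the parents instead is possible by calling
`filter_markers()` on the panel and rebuilding the hybrids, and which of the
two a given study used is usually not recoverable from its reports.

## Kernels

* VanRaden additive: `G_a = ZZ'/(2 Σ p_j q_j)`, columns centered at `2p_j`.
* Vitezica dominance: `G_d = WW'/Σ(2 p_j q_j)^2`, `W = d − 2 p_j q_j`.
* Gaussian (RKHS): `K = exp(−(m/h) D²)` on squared Euclidean row distances,
  one kernel per bandwidth multiplier `m ∈ {5, 1, 0.2}`, `h` the 5th
  percentile of the off-diagonal `D²` values.

Allele frequencies for both `G_a` and `G_d` are computed from the hybrid
matrix being kernelized (`p` can be overridden to use parental
frequencies). `D²` is used unscaled: because `h` is a percentile of the same
`D²`, the kernels are invariant to any common rescaling of the distances,
so dividing by marker count would change nothing. `h` uses only off-diagonal
entries — including the zero diagonal would bias the percentile toward 0 —
and the percentile uses R's default (type 7) linear interpolation, fixed for
reproducibility. Kernel averaging is realized in the sampler as three
simultaneous random effects with separate variances, not as a pre-averaged
matrix, so the data decide each bandwidth's weight.

G×E interaction kernels are record-level Hadamard products
`Z_E Z_E' ⊙ Z₁ K Z₁'`: the genotype kernel expanded to records, zeroed
between records from different environments. Schur's product theorem
guarantees these stay PSD, and `check_psd()` verifies every built kernel
numerically, bending (eigenvalue flooring) only when a matrix fails the
tolerance.

## Stage 1: per-environment REML

RCBD environments fit `value ~ rep (fixed) + genotype (random)`; augmented
environments fit `value ~ rep + is_check (fixed) + block (random) +
genotype (random)`. The augmented parameterization is a package choice:
study reports typically say "checks inside blocks and replications fixed"
without printing the full design-matrix construction, so we use a single
check-vs-entry fixed contrast, keep all genotypes (checks and entries) in
the random genotype term, and document that here rather than guessing a
specific software's internal coding. BLUEs come from the same model with
genotype fixed and sum-to-zero replicate contrasts, so the genotype
coefficients are adjusted means; on balanced RCBD data they reduce to raw
genotype means (verified in the tests).

Fitting is delegated to `lme4::lmer()`; the package additionally implements
the restricted log-likelihood surface directly (`reml_loglik()`: dense
`V = σ²_g Z_gZ_g' + σ²_p Z_pZ_p' + σ²_e I`, profiled fixed effects). Every
fit's reported log-likelihood is evaluated on this surface at the REML
estimates, which makes likelihood-ratio tests internally consistent and
gives the test suite an independent oracle: on small balanced data sets a
nested golden-section search over the variance ratio and residual variance,
using only `reml_loglik()`, reproduces the `lmer` estimates to 1e-4.

Negative variance estimates are truncated at zero (the usual REML boundary
behavior). The LRT for a random term uses a plain χ²(1) reference, the
convention of the workflow this package implements; because the null is on
the boundary this is conservative, and the 50:50 mixture p-value (half the
χ²(1) tail) is reported alongside. Heritability is not computed the same
way by all field software; we adopt the entry-mean definition
`h² = σ²_g/(σ²_g + σ²_e/r̄)` with `r̄` the harmonic-mean replicate count
(block variance excluded from the denominator), and a `type = "plot"`
variant `σ²_g/(σ²_g + σ²_e)` used when comparing against the simulator's
plot-level targets. Significance of BLUP correlations uses a two-sided
t-test — a package choice, flagged as such, since the test type behind
"significant correlation" is rarely stated.

## Stage 2: Gibbs sampler

The response is the stage-1 BLUE table. For every random term the kernel is
eigendecomposed once (eigenvalues below 1e-10 of the maximum dropped) and
the effect is sampled in the eigenbasis. When each record maps to a distinct
kernel row (single-environment fits) the full conditionals are diagonal and
the sweep is a pair of matrix–vector products; otherwise (record-level G×E
fits, hybrids without records) the precision is a dense m×m (single-trait)
or mt×mt (multi-trait) Cholesky solve. Both paths draw from the same joint
full conditional, so they differ only in cost.

Priors follow the defaults of the standard Bayesian genomic-regression
software in spirit, reimplemented because the upstream defaults are not
printed in most reports: every variance gets a scaled-inverse-chi-square
prior with 5 degrees of freedom and scale set so the prior mode equals an
equal share of 50% of the per-trait response variance across the genetic
terms, with the residual mode at the remaining 50%. Multi-trait covariances
get inverse-Wishart priors with `t + 4` degrees of freedom and a diagonal
scale matching the single-trait construction. The intercept and environment
fixed effects are flat. Missing responses — untested hybrids, missing
trait×environment cells — are imputed by data augmentation each sweep, which
is also how predictions for untested hybrids arise; equivalently, hybrids
with no records can be carried through `all_hybrids`, receiving genetic
values through the kernel alone. Chains store
`floor((n_iter − burn_in)/thin)` samples; the published settings
(30,000/3,000/10) store 2,700. A "totaling 2,700 iterations" statement is
interpreted as this stored-sample count.

Prediction for a new environment (CV0/CV00) uses the genetic main effects
only: additive values for A specs, additive plus dominance for AD specs,
interaction terms excluded — whether published accuracies for AD models used
breeding values only or total genetic values is ambiguous in most reports,
so both are supported (`include =`) and the AD default is `a + d`, reported
explicitly in `predict_genetic_values()`.

## Cross-validation

CV1 draws `k` equal folds (within one hybrid) uniformly without
stratification, re-randomized each repeat; accuracies are averaged over
folds within repeat, then over repeats, with the standard deviation
reported. CV0 trains on all records of the training environments and scores
the test environment; CV00 additionally removes every training record whose
hybrid occurs in the test environment. Accuracy compares predictions with
the test environment's full-data stage-1 BLUEs (stage 1 is upstream of the
CV, so fold-specific BLUE refits are not used). Traits absent from an
environment are simply absent from those runs.

## The synthetic-data generator

`simulate_scenario()` emulates the structure the analysis assumes: two
heterotic pools with independently drawn per-group allele frequencies from
a common range (a deliberately minimal divergence model — enough to make
inter-group crosses heterotic, with no claim about any real panel's
population genetics); inter-group factorial or full-diallel crossing;
trait architectures in correlated groups (defaults: 20 traits in 3 groups,
within-group genetic correlation 0.7, between 0.1, heritability targets
0.05–0.85 — qualitative mirrors of a fresh-market breeding program, not
exact values); additive + dominance marker effects with environment-specific
deviations following a configurable genetic correlation across environments
(default 0.6); and unbalanced trials — year-1 environments with large hybrid
sets under augmented (2 replications, 10 blocks) or RCBD designs, year-2
environments with small sets built by subsampling year-1 hybrids (overlap
fraction, default 0.6) plus new crosses, which is what makes CV0 and CV00
distinguishable. Residual noise is calibrated against the realized genetic
variance of the hybrid set so plot-level heritability matches each trait's
target; replicate and block effects default to 0.3 of the residual SD.
Random-number streams are split per component (genotypes, crossing plan,
effects, design, noise, folds, chains) so changing one does not perturb the
others, and every object is bit-reproducible under a fixed seed.

What the generator does *not* emulate: linkage and LD decay (markers are
exchangeable), selection over generations, pedigree structure beyond a
single cross, spatial field trends, and non-Gaussian trait scales (ratings
are simulated as continuous). Passing tests therefore demonstrate that the
estimators recover the generating model's structure, not that real data
meet these assumptions.

## Problem sizes used by the tests

The suite favors many small fits over few large ones: scenario fixtures use
24–62 parents, 300–1,000 markers and 80–300 hybrids; Gibbs chains in tests
run 400–5,000 iterations. These sizes were chosen as the smallest at which
each property is comfortably identifiable. Two calibration points worth
noting:

* Heritability recovery uses the stated design of 300 hybrids × 1,000
  markers × 20 simulations at a 0.5 plot-level target.
* The null-dominance check (ADG on purely additive data) uses a
  strong-signal design (200 hybrids, 600 markers, h² ≈ 0.8) because the
  additive and dominance relationship matrices of F1 hybrids of inbreds are
  intrinsically collinear (off-diagonal correlation ≈ 0.8 in these panels);
  at low signal the variance partition between them is weakly identified
  for any sampler.

## Known limitations

* Augmented-design BLUEs for unreplicated entries rest on the block-random,
  check-fixed parameterization above; other parameterizations give slightly
  different adjusted means.
* The multi-trait G×E path uses a dense per-eigenvalue (or Kronecker)
  solve; it is exact but quadratic-to-cubic in hybrids × traits, so it is
  intended for trait subsets (e.g. the traits shared across all
  environments), not 20-trait fits.
* No convergence diagnostics beyond stored-draw summaries are computed;
  chain settings are the user's responsibility.
* Marker effects are exchangeable across the genome; there is no
  BayesB/Cπ-style variable selection.
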