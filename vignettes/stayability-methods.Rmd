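---
title: "Single-step genomic evaluation of binary stayability traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation of binary stayability traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staygblup)
```

## The trait and the problem

Stayability measures whether a beef cow remains productive in the herd: a
female scores 2 (success) if she has produced a required number of calves by
a given age, and 1 (failure) otherwise. The five standard definitions are
two or three calvings by 48 months (`stay48_2`, `stay48_3`), two or three by
54 months (`stay54_2`, `stay54_3`), and three by 72 months (`stay72_3`). In
tropical *Bos indicus* herds where heifers are exposed at 10–14 months of
age, the early definitions support culling decisions years sooner than the
traditional 72-month definition, at the price of lower incidence (roughly
11–14% success against ~38%).

Because the trait is binary, a Gaussian linear model is misspecified; the
classical alternative is a threshold (liability) model: a latent normal
variable `l = Xb + Zu + e` determines the category through a fixed
threshold. This package implements both analyses in a single-step genomic
BLUP (ssGBLUP) framework, together with the machinery needed to connect
them: variance-component estimation by Gibbs sampling on the liability
scale, conversion of those components to the observed scale, and the LR
(whole versus partial data) method to compare predictive ability.

## Relationship matrices

* `build_A_inverse()` assembles the sparse inverse of the pedigree
  relationship matrix by Henderson's rules with inbreeding; inbreeding
  coefficients come from the Meuwissen–Luo ancestor recursion
  (`compute_inbreeding()`), which scales to very large pedigrees.
* `build_A22()` gives pedigree relationships among genotyped animals,
  either by the dense tabular method (small problems, also the test oracle)
  or by Colleau's indirect method, which multiplies A by indicator vectors
  through the gene-flow decomposition `A = T D T'` in O(n) per animal and
  never forms A.
* `build_G()` is VanRaden's method 1: `G = ZZ'` with allele counts centred
  at twice the observed allele frequency and scaled by `2 Σ p_j(1−p_j)`.
  Missing codes (5) are centred to zero, i.e. mean-imputed. The scaling
  divides the cross-product (equivalently Z by the square root): the
  familiar parameterisation in which the mean diagonal of G is near 1 under
  Hardy–Weinberg.
* `tune_G()` aligns G with `A22` by solving the two-moment system (mean
  diagonal and mean off-diagonal), and `blend_G()` then takes
  `0.95 G + 0.05 A22`. Tuning happens before blending: blending is the
  positive-definiteness guarantee and must act last.
* `apy_inverse()` implements the APY inverse of G: a dense inverse on a
  core subset plus a diagonal of conditional variances for non-core
  animals. With core = all animals it reproduces the dense inverse exactly;
  with a core at least as large as the effective rank of G it agrees to
  numerical precision. Core animals are drawn uniformly at random among the
  genotyped, under the run's seed.
* `assemble_H_inverse()` builds the single-step operator
  `H⁻¹ = A⁻¹ + [0, 0; 0, G⁻¹ − A22⁻¹]` as a matrix-free operator
  (`h_matvec()`), with dense and sparse realisations for small problems and
  for the Gibbs sampler.

## Solvers

The observed-scale linear model is solved by preconditioned conjugate
gradients on the mixed-model equations (`solve_mme()`), with a diagonal
preconditioner and the H-inverse applied as an operator. Phenotypes are
used exactly as coded (`{1,2}`); solutions are translation invariant, so
the coding constant is absorbed by the contemporary-group (CG) solutions.

The threshold model appears twice, deliberately mirroring how routine
evaluations are organised:

* **Variance components** come from a single-site Gibbs sampler
  (`run_gibbs()`) with liability augmentation: each record's liability is
  drawn from a truncated normal on its category's side of the threshold,
  location effects are updated equation by equation, and `σ²ᵤ` is drawn
  from its scaled inverse chi-square full conditional
  `(u'H⁻¹u + νS)/χ²(q+ν)`. Identifiability follows the standard binary
  convention: threshold fixed at 0 and residual liability variance fixed
  at 1. Priors default to flat on the variances (`ν = −2, S = 0`).
* **Breeding values at known components** come from a deterministic
  iteration-on-data EM solver (`solve_threshold_mme()`): replace each
  liability by its truncated-normal conditional mean given the current
  fitted value, then re-solve the liability-scale mixed-model equations by
  PCG, and iterate to convergence. This is the analogue of the nonlinear
  iteration-on-data solvers used for large categorical evaluations, and it
  is free of Monte-Carlo noise — which matters for the LR statistics below,
  where sampling noise in posterior-mean breeding values visibly deflates
  the dispersion coefficient.

One numerical point deserves a note: with flat priors on CG effects, groups
containing only one category (likely at 14% incidence) make the liability
model's posterior improper in those directions — the classic extreme-category
problem. The threshold-mode default is therefore a vague proper Gaussian
prior on CG effects (`beta_prior_var = 4` on a liability scale whose total
variance is near 1.3), consistent with writing the systematic effects as
`b ~ N(0, Iσ²β)`. The linear mode keeps flat fixed effects.

Truncated normal draws use the inverse-CDF method with log-space tail
probabilities, so bounds tens of standard deviations from the mean remain
exact rather than collapsing to infinity.

## Scale conversion

Variance components estimated on the liability scale are converted to the
observed scale by Robertson's formula for binary traits:
`h²_obs = z² h²_l / (α(1−α))`, with `α` the success incidence, `t` the
normal quantile at `1−α` and `z` the normal density at `t`. The observed
additive and phenotypic variances are `z² h²_l` and `α(1−α)`, and the
observed residual variance is `σ²ₚ − (σ²ᵤ + σ²ₚₑ + σ²cg)` — the
parenthesisation matters and is fixed by requiring internal consistency of
the reference summaries this machinery reproduces (e.g. 0.123 − 0.010 =
0.113). Permanent-environment and CG variances are zero in the
single-record animal model used here. `α` is defined as the incidence of
the success category; the formula is symmetric in `α` versus `1−α`, so the
choice only affects reporting.

## Convergence diagnostics

`geweke_z()` compares the mean of the first 10% of a chain against the last
50%, standardised by spectral-density-at-zero variance estimates from
non-overlapping batch means (batch size about √n, at least 20 batches). The
two-sided p-value uses a Student reference with Welch–Satterthwaite degrees
of freedom: with the modest number of batches a normal reference is
measurably liberal, while the Student form is calibrated to the nominal 5%
(0.9505 pass rate over 2,000 null replicates). Chains with p below 0.05 are
flagged as non-converged. Posterior summaries report means, SDs and 95%
highest-posterior-density intervals (shortest window of the sorted draws).

## The LR validation method

`make_partial()` removes the last `cutoff_years` (default 2) of records by
record year and defines focal animals: genotyped females whose own record
falls in the removed window and who have no progeny records in the partial
data. `run_lr_experiment()` fits the chosen model on whole and partial data
with identical settings and variance components and computes, over focal
animals,

* accuracy `acc = cov(û_w, û_p) / sqrt((1−F̄) σ̂²ᵤ)`,
* bias `δ = (mean(û_p) − mean(û_w)) / σ̂ᵤ`,
* dispersion `b₁ = cov(û_w, û_p) / var(û_p)`,
* correlation `corr = cov(û_w, û_p) / sqrt(var(û_w) var(û_p))`,

with sample moments on `n−1` denominators. Two policy choices were open and
are fixed as follows: `σ̂²ᵤ` in the accuracy denominator is the whole-data
estimate on the scale of the model being validated (the better-informed
estimate, constant across compared models), and records are truncated by
the year the phenotype becomes available rather than by birth year (the
two coincide up to a constant for single-record age-defined traits).
A negative whole/partial covariance is reported as zero accuracy with a
warning.

## The synthetic-data generator

The real data behind this class of analysis are private herd books, so the
package ships a generator that reproduces their statistical structure at
desk scale:

* `simulate_pedigree()` — discrete generations of constant size; each
  generation uses a restricted set of sires (10% of males by default) so
  inbreeding accrues as in a finite breeding population; two birth years
  per generation.
* `simulate_genotypes()` — founder genotypes Hardy–Weinberg at frequencies
  uniform in `maf_range`, then gene dropping (one allele transmitted per
  parent).
* `sim_truth()` — additive variance `h²/(1−h²)` against a unit residual
  liability variance. Breeding values are built from marker effects by
  default (`u = Σ z α`, `α ~ N(0, σ²ᵤ/Σ2p(1−p))`), so genotypes carry real
  signal for downstream prediction. For parameter-recovery studies of the
  pedigree-based sampler, `method = "pedigree"` instead gene-drops breeding
  values so their covariance is exactly `Aσ²ᵤ`, matching the fitted model's
  assumption; with marker-based values and a deep, small population,
  drift and linkage make the marker covariance exceed A among collateral
  relatives and a pedigree-only analysis genuinely overestimates `σ²ᵤ` —
  an effect of the generator, not of the sampler.
* `assign_contemporary_groups()` — farm × management group × birth year ×
  season (dry April–September, rainy October–March) with multinomial
  assignment; CG effects `N(0, 0.10)` on the liability scale; groups with
  fewer than 3 records are dropped from analyses (`drop_small_cgs()`).
* `simulate_calving_histories()` — annual breeding opportunities from first
  exposure at 10–14 months; conception at opportunity k is a probit event
  `Φ(μₖ + u + cg + ε)` and a conception yields a calving age (exposure + 2
  months mid-season + 9 months gestation + 12 months per later
  opportunity). The default per-opportunity base rates
  `(0.13, 0.23, 0.38, 0.80, 0.90)` were calibrated once by Monte Carlo so
  the realised STAY48-2 incidence sits near 14% and STAY72-3 near 38%, the
  regime of large Nellore programmes, and are not meant to be re-tuned.
* `simulate_binary_trait()` — a single-liability binary record per animal,
  i.e. the threshold model's own generative process, used where the
  fitted model must be correctly specified (recovery and LR studies).

What the generator does **not** reproduce: the near-equality of the 2- and
3-calving incidences seen in real data (13.0% versus 14.4% by 48 months),
which implies a conception persistency far stronger than a liability model
with h² ≈ 0.2 induces across opportunities; culling for non-reproductive
reasons; selection (matings are random, so LR validation is free of
selection bias by construction); and genotyping strategies other than
"genotype the youngest generations". Passing tests on these data therefore
demonstrate internal correctness of the estimators under the model's
assumptions, not robustness to selection or misspecification in real herd
books.

## Problem sizes and numerical choices

The test and demonstration configurations were chosen as the smallest
problems that still identify the quantities of interest: parameter-recovery
runs use ~5,000 binary records on a 5,000-animal, 4-generation pedigree
with contemporary groups of ~80 records (mirroring the per-CG record counts
of the real data structure — small CG subclasses are a known source of
upward bias in threshold-model variance estimates), chains of 20,000
iterations with 5,000 burn-in and thinning of 10; production-scale settings
(300,000 / 100,000 / 100) remain available through `gibbs_config()`. LR
experiments use ~5,500 animals with the youngest generation (~1,100
animals) genotyped, giving ≥ 500 focal females. PCG iterates to a relative
residual of 1e-12 (1e-9 inside the EM threshold solver, whose outer loop
converges on fitted liabilities to 1e-6). Degenerate inputs — empty
contemporary groups, all-missing markers, non-positive APY conditional
variances, cyclic pedigrees — are hard errors with specific messages rather
than silent repairs.

## A worked pipeline

```{r pipeline, eval = FALSE}
cfg <- sim_config(n_founders = 1000, n_generations = 4, n_snps = 1600,
                  n_farms = 3, n_mgmt_groups = 1, seed = 42)
res <- run_pipeline(cfg, out_dir = "stay_run", trait = "binary",
                    gibbs_cfg = gibbs_config(n_iter = 6000, burn_in = 2000,
                                             thin = 4, seed = 42),
                    genotyped_generations = 1)
res$posterior     # liability-scale components with HPD intervals
res$conversion    # observed-scale equivalents
res$validation    # LR statistics for threshold and linear models
```

Two desk-scale cautions apply to variance components from the genomic
(H-based) threshold analysis. First, keep the marker count comfortably
above the number of genotyped animals: with a rank-deficient G the
genotyped block has fewer effective dimensions than animals and the
`σ²ᵤ` full conditional is attenuated towards zero. Second, marker-derived
breeding values of *ungenotyped* ancestors are represented by pedigree
relationships only approximately; in small deep pedigrees this pulls the
estimate upward (in the example above, 0.32 with HPD 0.22–0.44 against a
simulated 0.20). Both effects vanish at the marker and record numbers of
production evaluations, and neither affects analyses run at fixed variance
components (the LR fits) or the pedigree-only sampler.

The run directory contains every intermediate file (pedigree, genotypes,
phenotypes, QC report, posterior summaries, validation statistics and a
combined report), so each reported number can be recomputed from the files
on disk.

## Known limitations

* The Gibbs sampler is single-site; for very large genotyped sets the
  dense genotyped-block of H⁻¹ dominates its per-iteration cost. The APY
  path removes the dense inverse but the sampler still touches every
  nonzero per sweep.
* The threshold machinery is binary-only; the multi-category extension of
  the scale transformation and the sampler are out of scope.
* Unknown-parent groups, metafounders, maternal and permanent-environment
  effects are not implemented, matching the single-record animal model
  this package targets.
* `reliability_proxy()` inverts the dense coefficient matrix and is meant
  for small problems only; the LR method is the validation instrument.
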