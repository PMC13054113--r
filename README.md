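# staygblup

Single-step genomic BLUP (ssGBLUP) for binary **stayability** traits —
whether a beef cow has produced a required number of calves by a given age
(e.g. `stay48_2`: two calvings by 48 months, success coded 2, failure 1).
The package is aimed at quantitative geneticists who want a complete,
testable desk-scale implementation of the workflow used in large tropical
beef-cattle evaluations:

* pedigree machinery: Meuwissen–Luo inbreeding, Henderson's sparse A⁻¹,
  tabular and Colleau A22;
* genomic machinery: VanRaden method-1 G, two-moment tuning against A22,
  95/5 blending, APY inverse, and the single-step operator
  `H⁻¹ = A⁻¹ + [0,0; 0, G⁻¹ − A22⁻¹]`;
* an observed-scale linear model solved by preconditioned conjugate
  gradients, and a liability-scale threshold model: Gibbs sampling with
  data augmentation for variance components, plus a deterministic
  iteration-on-data EM solver for breeding values at known components;
* Robertson's liability ↔ observed scale conversion
  `h²_obs = z² h²_l / (α(1−α))`;
* the LR validation method (whole versus partial data) with accuracy,
  bias, dispersion and correlation on focal animals;
* a synthetic-data generator (pedigree, gene-dropped SNP genotypes,
  contemporary groups, calving histories scored into the five standard
  stayability definitions) so the entire pipeline runs without private
  herd-book data.

## Worked example

```r
library(staygblup)

# scale conversion from reference inputs: liability h2 = 0.20,
# success incidence 26,152 / 182,064
conv <- liability_to_observed(0.20, 26152 / 182064)
print(conv)
#> Liability -> observed scale at incidence 0.1436 (t = 1.0646, z = 0.2263)
#>   h2 liability  : 0.2000
#>   h2 observed   : 0.0834
#>   sigma_u2 obs  : 0.0103
#>   sigma_p2 obs  : 0.1230
#>   sigma_e2 obs  : 0.1128
```

At the table precision used in routine reports these are 0.08, 0.010 and
0.113: the observed-scale heritability of a 14.4%-incidence binary trait is
less than half its liability-scale value, which is why rankings are made on
the liability scale and transformations are only used to move components
onto the scale of a linear evaluation.

A full synthetic run — simulate, QC, relationship matrices, threshold-model
Gibbs, scale conversion, and LR validation of both models (about a minute
on one core):

```r
cfg <- sim_config(n_founders = 1000, n_generations = 4, n_snps = 1600,
                  n_farms = 3, n_mgmt_groups = 1, seed = 42)
res <- run_pipeline(cfg, out_dir = "stay_run", trait = "binary",
                    gibbs_cfg = gibbs_config(n_iter = 6000, burn_in = 2000,
                                             thin = 4, seed = 42),
                    genotyped_generations = 1)
res$posterior
#>   parameter      mean         sd hpd_lower hpd_upper
#> 1  sigma_u2 0.4909737 0.13419438 0.2742268 0.7774417
#> 2  sigma_e2 1.0000000 0.00000000 1.0000000 1.0000000
#> 3        h2 0.3242011 0.05710451 0.2173743 0.4385370
res$validation
#>       model  trait n_focal   accuracy        bias dispersion correlation
#> 1 threshold binary     486 0.04515951 0.045201769  0.7697247   0.4863455
#> 2    linear binary     486 0.01046165 0.001977637  0.7891953   0.4788129
```

Here 2,501 females carry a binary record of 16% incidence in 60
contemporary groups; the youngest generation (1,250 animals, 486 focal
females) is genotyped. The liability-scale heritability is estimated at
0.32 (95% HPD 0.22–0.44) against a simulated value of 0.20 — at this desk
scale the pedigree part of H represents marker-derived breeding values of
ungenotyped ancestors only approximately, which pulls the estimate up; the
effect shrinks with marker number and data size (see the methods
vignette). Both models' LR dispersion sits below 1 because the validation
re-uses that inflated component estimate: under-shrunk partial predictions
are over-dispersed. `res$conversion` holds the observed-scale equivalents,
and `stay_run/` every intermediate file (pedigree, genotypes, phenotypes,
QC report, posterior summary, validation table), so each reported number
can be recomputed from disk. The methods vignette
(`vignettes/stayability-methods.Rmd`) documents the models, priors,
numerical choices and the generator's scope.

A thin command-line wrapper over the same functions is available:

```sh
Rscript inst/scripts/run_pipeline.R --founders 1000 --generations 4 \
    --snps 1600 --trait binary --seed 42 --out stay_run
```

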