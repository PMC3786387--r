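# cognest

Nested-domain robust Bayesian regression for biomarker–cognition studies.

## What this is for

Cross-sectional ageing studies often relate one blood biomarker — here
serum S100B, an astroglial calcium-binding protein proposed as a marker of
CNS integrity — to a battery of neuropsychological outcomes grouped into
cognitive domains (verbal ability, Stroop, secondary memory, primary
memory, perceptual speed).  Testing 18 outcomes separately invites
wrong-sign (type S) and exaggerated-magnitude (type M) errors.  `cognest`
implements the hierarchical alternative: outcome-level slopes are partially
pooled toward domain-level slopes, which are pooled toward one overall
slope, with robust Student-t errors.

For participant *i*, outcome *j* in domain *d(j)* (all variables
standardized, lower-is-better scores sign-inverted first):

```
y_ij ~ t_nu( alpha_j + theta_j * x_i + c_i' gamma_j , sigma_j )
theta_j = beta + delta_d(j) + eps_j
delta_d ~ N(0, sigma_D^2),  eps_j ~ N(0, sigma_O^2)
```

with N(0, 100²) priors on beta, intercepts and covariate effects,
half-Cauchy(0, 25) priors on sigma_D and sigma_O, Uniform(0, 100) on each
sigma_j, and Uniform(0.001, 0.5) on 1/nu.  Inference runs on a built-in
adaptive Metropolis-within-Gibbs sampler (compiled core) with
Gelman–Rubin, effective-sample-size and highest-density-interval
diagnostics.

Because the reference cohort's participant-level data were never deposited,
the package ships a synthetic-cohort generator moment-matched to the
published summary table (n = 219, 141 female; S100B mean 0.24 ng/mL, SD
0.14; a weak negative NART–S100B association of −0.004 ng/mL per error)
with known ground truth for parameter-recovery studies.

## Worked example

```r
library(cognest)

g <- generate_cohort(generator_config(seed = 1))   # known truth: beta = 0.15
cohort <- apply_exclusions(g$cohort)               # MMSE < 24 rule
post <- run_mcmc(model_spec(), build_analysis_matrix(cohort),
                 mcmc_config(preset = "reduced", seed = 1))
summarize_posterior(post, c("beta", paste0("domain[", 1:5, "]"), "nu"))
```

```
 parameter   mean     sd hdi80_lower hdi80_upper hdi95_lower hdi95_upper psrf  ess
      beta  0.209 0.0532       0.154       0.261       0.109       0.313    1 6110
 domain[1]  0.174 0.0330       0.135       0.218       0.106       0.236    1 7960
 domain[2]  0.223 0.0329       0.182       0.264       0.161       0.288    1 6160
 domain[3]  0.156 0.0280       0.121       0.192       0.103       0.212    1 3820
 domain[4]  0.269 0.0517       0.198       0.331       0.171       0.369    1 2270
 domain[5]  0.219 0.0543       0.150       0.284       0.113       0.330    1 7900
        nu 10.900 1.8300       8.440      12.700       7.700      14.500    1 4100
```

The overall standardized slope `beta` is estimated at 0.21 with a 95% HDI
of [0.11, 0.31], covering this cohort's generating value of 0.15; every
domain slope is positive; `nu` around 11 says the residuals are moderately
fat-tailed (the generator uses t₈ noise).  All PSRFs are at 1.00 and every
ESS clears 1000.

Covariate associations in natural units:

```r
covariate_regression(cohort, "nart", mcmc_config(preset = "test", seed = 2))
#> NART: slope -0.0062 ng/mL per error, 95% HDI [-0.0088, -0.0033]
```

`run_full_analysis()` does all of the above at once — the nested model
under three covariate sets (none; age + sex; age + sex + NART) plus the
three covariate regressions — and `export_reports()` writes the 72-row
slope table and the covariate table as TSV and JSON.  Command-line
wrappers live in `inst/cli/` (`synth-cohort.R`, `run-analysis.R`).

## Package layout

- `R/cohort_io.R` — cohort CSV input/output, exclusion rules, score
  inversion, standardization, the analysis matrix
- `R/calibration.R`, `R/synthetic.R` — published-cohort calibration
  constants and the moment-matched generator
- `R/model.R` — priors, model specification, reference log densities
- `R/sampler.R`, `src/sampler.cpp` — adaptive Metropolis-within-Gibbs
- `R/diagnostics.R` — HDI, Gelman–Rubin PSRF, effective sample size
- `R/report.R` — covariate-variant orchestration and report export
- `vignettes/nested-domain-model.Rmd` — model, sampler and generator
  design notes
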