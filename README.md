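# psen1traj

Trajectory-divergence modelling for *PSEN1* variant-domain groups in
autosomal-dominant Alzheimer disease (ADAD).

*PSEN1* pathogenic variants cause ADAD with near-complete penetrance, yet
carriers differ widely in how fast cognition and brain structure decline.
`psen1traj` implements a reusable pipeline for one candidate explanation:
whether the variant strikes a **transmembrane (TM)** helix or a
**cytoplasmic (CY)** segment of presenilin-1. It is written for
biostatisticians and ADAD researchers who want to run this analysis on
cohort data of the usual long format (one row per participant-visit), or to
study its statistical behaviour on simulated cohorts with known ground
truth.

## The model

For an outcome \(y_{ijt}\) (MMSE, CDR-SB, ICV-adjusted bilateral
hippocampal volume, composite PiB SUVR, CSF analytes) observed in subject
*j* of family *i* at expected years to symptom onset (EYO)
\(e = \text{age} - \text{expected AAO}\):

\[
y_{ijt} = \beta_0 + \mathbf{x}_{ijt}'\boldsymbol\gamma
        + \sum_k f_k(e_{ijt})\,\beta_k
        + \sum_k f_k(e_{ijt})\,\delta_{k,g(j)}
        + \alpha_{g(j)} + u_i + \varepsilon_{ijt}
\]

where \(f_k\) are the restricted-cubic-spline basis columns of EYO (knots
at the 0.10/0.50/0.90 empirical quantiles; the linear form drops the
nonlinear column), \(g(j) \in \{\text{NC}, \text{CY}, \text{TM}\}\),
\(\mathbf{x}\) holds sex, APOE &epsilon;4, age at visit and (for
clinical/cognitive outcomes) education, \(u_i\) is a family random
intercept, and estimation is by maximum likelihood (`lme4`). A
likelihood-ratio test decides per outcome whether the nonlinear ("cubic")
terms are retained. The **divergence point** is the earliest EYO at which
the 99% credible interval of the posterior TM&minus;CY difference curve
excludes zero and keeps excluding it at every later grid point. Mediation
of group differences in cognition by hippocampal volume (product of
standardized coefficients, family-stratified percentile bootstrap) and
TM-vs-CY comparison of per-subject annualized slopes past the divergence
point complete the pipeline.

## Worked example

Everything below runs on a synthetic cohort with the default study
structure (202 non-carriers, 65 CY, 135 TM carriers, family clustering,
longitudinal follow-up) and known ground truth:

```r
library(psen1traj)

sim  <- simulate_cohort(sim_config(seed = 42))
prep <- assemble(sim$cohort)              # EYO, ICV adjustment, PiB composite
#> Warning messages:
#> 1: 300 mmse value(s) outside [0, 30]
#> 2: 479 cdr_sb value(s) outside [0, 18]
```

The warnings are expected on simulated data: measurement noise is drawn
around range-clamped mean curves, so a few scores fall past the instrument
bounds; `assemble()` reports rather than truncates (use `strict = TRUE` to
make range violations errors).

```r

fit <- fit_eyo_lmem(prep, "mmse")         # spline LMEM, family intercept
fit
#> EYO trajectory LMEM (rcs EYO, ML) for 'mmse'
#>   n = 1204 observations in 215 families; logLik = -2237.94
#>   knots: -19.10, -5.93, 9.38
#>   var(family) = 0.5428, var(resid) = 2.078

group_contrast(fit, groups = c("TM", "CY"), term = "eyo2")
#> TM vs CY cubic EYO interaction: B [SE] = -0.419 [0.054], p = 1.1e-14

divergence_analysis(prep, "mmse", n_draws = 4000, seed = 43)
#> Divergence of TM - CY (99% credible interval, 4000 draws):
#>   first persistent divergence at EYO = -5.7 years
```

The negative cubic interaction says TM carriers lose MMSE points faster
than CY carriers as EYO increases; the divergence analysis places the first
credible separation 5.7 years before expected onset. The generating truth
in this simulation put the TM/CY split at EYO &minus;4; the gap between the
two numbers is the smoothing behaviour discussed in the methods vignette
(`vignettes/trajectory-divergence.Rmd`). Downstream:

```r
mediate_groups(prep, "mmse", "hv", n_boot = 1000, seed = 44)
#> Mediation of TM-vs-CY differences in 'mmse' by 'hv' (n = 200)
#>   direct           beta = -0.288  p = 0.000498
#>   mediator         beta =  0.621  p = <2e-16
#>   residual direct  beta = -0.225  p = 0.000485
#>   indirect (a*b)   beta = -0.063  95% bootstrap CI [-0.154, 0.028]
#>   -> not consistent with full mediation

sl <- subject_slopes(prep, "mmse")
compare_slopes(sl, threshold_eyo = -5.7)
#> Annualized slopes, TM vs CY (baseline EYO >= -5.7, welch t-test)
#>   TM: n = 46, mean = -1.578 (SD 0.924) per year
#>   CY: n = 21, mean = -1.132 (SD 0.441) per year
#>   t(64.8) = -2.67, p = 0.00961
```

Betas are in outcome-SD units (group indicator unstandardized). Hippocampal
volume does *not* fully mediate the MMSE difference here — correctly so, as
the simulator draws the two outcomes' trajectories independently. The slope
comparison shows TM carriers declining about 0.45 MMSE points per year
faster than CY carriers among subjects past the divergence point.

Variant classification and the codon-200 alternative grouping:

```r
classify_variant(c("A79V", "M146L", "E280A"))
#>   codon group codon_group
#> 1    79    CY      pre200
#> 2   146    TM      pre200
#> 3   280    CY     post200
```

A command-line wrapper over the same functions lives in
`inst/cli/psen1traj.R` (subcommands `simulate`, `classify`, `prepare`,
`fit`, `diverge`, `mediate`, `slopes`, `report`); a seeded chain is
byte-reproducible.

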