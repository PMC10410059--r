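---
title: "Modelling trajectory divergence between PSEN1 variant-domain groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trajectory divergence between PSEN1 variant-domain groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psen1traj)
```

## The scientific question and the model

Autosomal-dominant Alzheimer disease (ADAD) caused by *PSEN1* pathogenic
variants is nearly fully penetrant, yet carriers decline at very different
rates. One candidate explanation is *where* in the protein the variant
falls: the nine transmembrane (TM) helices participate directly in
gamma-secretase's intramembrane proteolysis, while the cytoplasmic (CY)
segments are involved in substrate recruitment and retention. `psen1traj`
implements a pipeline for asking whether TM-variant carriers and CY-variant
carriers follow different clinical, cognitive and biomarker trajectories
over *expected years to symptom onset* (EYO; visit age minus the expected
age at onset for the carrier's family/variant, negative before onset).

The central estimator, `fit_eyo_lmem()`, is a linear mixed-effects model
fitted by maximum likelihood with `lme4`:

* the outcome (MMSE, CDR-SB, ICV-adjusted bilateral hippocampal volume,
  composite PiB SUVR, CSF analytes) is regressed on EYO, either linearly or
  through a restricted cubic spline with knots at the 0.10/0.50/0.90
  empirical EYO quantiles (three knots give one nonlinear basis column, so
  "linear" and "cubic" EYO-by-group interaction terms each name a single
  coefficient);
* group (NC/CY/TM, non-carriers as reference; or pre-/post-codon-200)
  enters as a main effect plus an interaction with every EYO basis column;
* covariates are sex, APOE e4 status, age at visit, and years of education
  for the clinical/cognitive outcomes; the pathology-adjusted sensitivity
  model adds the PiB composite and CSF p-tau181 as fixed effects
  (`extra_covariates`);
* a family-level random intercept absorbs shared variance among siblings.

ML rather than REML is used throughout so that the likelihood-ratio choice
between the linear and spline EYO forms (`lrt_select()`, alpha = 0.05,
configurable) compares fixed-effect structures validly and reported
estimates come from the same fit. Inference on single coefficients and on
linear contrasts (`wald_contrast()`, `group_contrast()`) uses the normal
reference rather than a degrees-of-freedom approximation; with hundreds of
observations per model the difference is negligible, but p-values for small
subgroups should be read with that limitation in mind. TM-vs-CY contrasts
computed as linear combinations agree with refitting under a CY reference
level to numerical precision (this is tested). Benjamini-Hochberg
adjustment is applied across CSF analytes via `bh_adjust()`.

## The divergence point

The headline quantity is the earliest EYO at which the TM and CY expected
trajectories separate. `posterior_draws()` samples the fixed-effect vector
from its normal-approximation posterior: the ML estimate and covariance are
combined by precision weighting with independent weakly-informative
normal(0, 10 x sd(outcome)) priors; half-normal-style positivity is
inherited from the ML variance components, which are held fixed. For the
sample sizes this package targets the posterior of the fixed effects is
very close to normal, and the draws agree with the ML fit to within 0.1
standard error (tested). Draws are organised into chains only to compute
split-chain convergence diagnostics and effective sample sizes, which are
attached to every result; sampling is deterministic given the seed, and a
prior-predictive mode (`prior_only = TRUE`) reproduces the prior moments.

`difference_curves()` evaluates, for every draw, the TM-minus-CY difference
in expected outcome on an EYO grid (default -25 to +10 in 0.1-y steps,
clipped to the observed EYO support; divergence is never extrapolated).
Covariate terms cancel algebraically, so the curves depend only on the
group main effect and the group-by-EYO interactions. `divergence_point()`
takes equal-tailed credible intervals (99% by default; HPD by flag) at each
grid point and reports the earliest grid point at which the interval
excludes zero *and keeps excluding zero at every later grid point*. The
persistence rule resolves what "first point of divergence" means when the
band brushes zero transiently; without it a single noisy grid point could
declare divergence.

### What the divergence estimate does and does not localise

The divergence point is a property of the *spline-smoothed* fitted curves,
not of the generating hinge, and it inherits two opposite biases that the
test suite measures rather than hides:

* **Weak effects are detected late.** When the TM-CY gap is a linear ramp
  reaching one residual SD at EYO 0 with 400 carriers, the 99% band still
  covers zero where the true gap is below ~0.2 residual SD, and the median
  first persistent exclusion lands about 1.8 y after the true hinge
  (recovery distribution measured over 100 seeded replicates in the test
  suite). This is detection power, not estimator error: recomputing the
  bounds exactly from the normal posterior, with no Monte-Carlo error,
  gives the same median.
* **Strong smooth effects are detected early.** A three-knot restricted
  spline cannot represent a hinge; a large late gap leaks backwards through
  the global basis, so the fitted difference can exclude zero before the
  generating divergence EYO. On the default synthetic cohort the MMSE
  divergence is reported several years before the generating hinge for
  exactly this reason.

Null calibration, by contrast, is clean: with identical TM and CY curves a
divergence is reported in at most 5% of 200 replicates at the 99% level
(tested), because under the persistence rule a false report requires the
band to exclude zero at the final grid point.

## The synthetic cohort and its ground truth

Because the real observational data are available only by application, the
package ships a first-class simulator. `sim_config()` defaults encode the
cohort structure the pipeline targets: 202 non-carriers, 65 CY and 135 TM
carriers; families of 1-4 enrolled members (family random intercepts);
baseline EYO uniform on -25..+10 y; 1-6 visits about 1.4 y apart, for a
mean follow-up near 3 y; expected age at onset drawn per family around 46.6
(SD 7) y; sex ~ Bernoulli(0.58 female), APOE e4 ~ Bernoulli(0.30),
education ~ truncated normal(15, 2.8) on [6, 22]. Carrier codons are drawn
uniformly from the matching intervals of the packaged PSEN1 topology table,
so classification round-trips.

Group mean curves are built from three parts per outcome: a non-carrier
line (level plus a mild per-year drift); a carrier departure shared by CY
and TM — a hinged cubic that is zero before the hinge, reaches
`carrier_delta` at EYO 0 and continues linearly afterwards, a natural-
spline-style tail chosen so the sigmoid-like shape stays bounded; and a
TM-only hinged ramp that switches on at the true divergence EYO
(`tm_divergence`), making TM and CY means *identical* below it by
construction. The mean curve is clamped to the instrument range (MMSE
0-30, CDR-SB 0-18); Gaussian noise is added after clamping, so observed
values can exceed instrument bounds the way rating noise does, and
`assemble()` flags (warning by default, error with `strict = TRUE`) rather
than silently truncates. Family, subject and visit-level noise components
are drawn independently per outcome. One RNG stream is split by purpose
(structure, covariates, noise), so changing the visit schedule does not
perturb covariate draws. Covariate effects default to zero, which makes the
generating curves the exact marginal group means — the property every
recovery test leans on. Raw measurement columns mimic what an imaging/CSF
pipeline would deliver: left/right hippocampal volumes around the latent
bilateral mean with an ICV coupling slope of 0.0015, fourteen regional
SUVRs around the latent PiB composite, and CSF analytes.

What the simulator does *not* emulate: scanner or assay batch effects,
informative dropout, practice effects, measurement floors at the item
level, families mixing carriers and non-carriers (families are nested in
group here), or the upstream EYO construction from mutation-specific versus
parental onset ages (EYO is generated directly; in real data the expected
AAO is an input column). Passing tests therefore demonstrate that the
statistical machinery recovers what it claims from data satisfying the
model's assumptions — not that those assumptions hold in any real cohort.

The controlled experiments in the test suite use deliberately simple
special cases of the generator: linear-truth cohorts (the TM departure a
full-range linear ramp, so the linear LMEM is exactly specified) for
coefficient recovery, and ramp-divergence cohorts for the divergence
experiments. In the divergence recovery and null-calibration experiments
all between-person variance is collapsed into the visit-level residual
(family and subject SDs set to 0) so that the stated effect size — a ramp
reaching one *residual* SD at EYO 0 — is also the effect size relative to
total noise; with additional variance components of realistic size the same
experiment measures a smaller standardised effect and detection shifts
about 2 y later, which we report rather than re-scale.

## Preprocessing choices

* Bilateral volumes are averaged, then ICV-adjusted by the residual method:
  `adjusted = volume - slope (icv - mean(icv))`, with the slope estimated
  on the full analysis sample by default (`icv_sample = "nc"` restricts
  estimation to non-carriers). The adjustment preserves the sample mean.
* The PiB composite is the unweighted mean of 14 regional SUVRs (7 cortical
  regions x 2 hemispheres); any missing region gives a missing composite.
* Categorical coding: sex F, APOE e4 non-carrier, group NC as references,
  so every reported contrast reads relative to non-carriers unless
  explicitly refit.
* Complete-case analysis per outcome; no imputation. `assemble()` never
  drops a row silently — every exclusion lands in the `"exclusions"`
  attribute with subject ID and reason, and re-running `assemble()` on its
  own output is the identity (tested).
* Variant classification is a pure interval lookup on a plain-text domain
  table with UniProt P49768 topology provenance; lumenal segments are
  labelled `other` and classify as `unclassified`, as do unparseable
  protein-change strings (with a warning). Variants spanning domain
  boundaries (insertions/deletions) are assigned by their single reported
  codon; that limitation is inherent to the codon-interval representation.
  The codon-200 alternative grouping takes "before codon 200" as
  codon < 200, so codon 200 itself is `post200`.

## Mediation and longitudinal slopes

`mediate_groups()` asks whether TM-vs-CY differences in hippocampal volume
statistically account for TM-vs-CY differences in cognition, with three
standardized regressions on baseline visits (one row per subject): outcome
on group; outcome on mediator plus group; mediator on group — all with the
trajectory-model covariate set by default. The indirect effect is the
product of the group-to-mediator and mediator-to-outcome paths, and for
nested linear fits the exact identity `direct = residual_direct + indirect`
holds (asserted to 1e-6). Uncertainty comes from a percentile bootstrap
(default 5000 replicates) that resamples whole families within group
strata; z-scoring uses the original analysis sample throughout, so
bootstrap replicates estimate the sampling distribution of the same
standardized quantities. "Full mediation" is declared when the direct
effect is significant, the residual direct effect is not, and the indirect
CI excludes zero. In the degenerate zero-noise chain the mediator absorbs
the group column exactly; the aliased residual direct effect is reported as
0 with an `aliased` flag.

`subject_slopes()` extracts per-subject annualized rates of change by
ordinary least squares on years since each subject's first visit (BLUP
slopes from a random-slope model are available as a sensitivity flag);
subjects without two distinct time points are excluded and logged.
`compare_slopes()` restricts to subjects whose baseline EYO is at or past a
threshold — by design an explicit input, typically the cross-sectional
divergence point — and compares TM and CY slopes with Welch's t-test
(pooled-variance Student by flag; the published integer degrees of freedom
do not determine the flavour, so the unequal-variance default is the safer
one).

## Numerical and reporting choices

* Knots require at least 10 distinct values and strictly increasing
  quantiles; ties produce an error advising the linear form. The nonlinear
  spline column is normalised by the squared knot span, the conventional
  scaling that keeps all basis columns on the scale of EYO.
* Zero-variance boundaries: `lme4` singular fits are accepted and flagged
  (`$singular`), never silently altered; the `converged` flag reports
  optimizer messages honestly.
* Demographics tables use unadjusted pairwise t and chi-square tests
  (no continuity correction by default, Yates by flag), mirroring the
  baseline-characteristics convention; groups with fewer than two subjects
  suppress tests with a warning.
* `run_report()` writes, per stage, a full-precision CSV and a
  fixed-precision formatted twin, plus the configuration, seed, package
  version and a manifest; nothing in an archive depends on wall-clock
  time, so a seeded pipeline reproduces every file byte-for-byte (tested
  through the CLI dispatcher).
* Test-suite problem sizes were chosen to make Monte-Carlo conclusions
  stable at fixed seeds: 100 replicates for coefficient and divergence
  recovery, 200 for null calibration and slope power, 1000 basis/BH oracle
  cases, cohorts of 300-900 subjects for single-fit checks.

## Known limitations

* Normal-approximation posterior: credible intervals ignore uncertainty in
  the variance components and any posterior skew; with small families or
  few carriers an HMC sampler could differ. The package treats the sampler
  as an implementation contract — any sampler matching the ML fit at large
  n and passing null calibration is admissible — and the shipped one is the
  fastest member of that class.
* The divergence point localises the first *detectable* separation of
  smoothed curves (see above), so its bias depends on effect size; compare
  against `truth_difference_curve()` when simulating.
* Normal-reference p-values, single family-level random intercept, and
  simultaneous inclusion of age and EYO (near-collinear when onset ages
  vary little; a warning fires at |r| > 0.95 and `include_age = FALSE` is
  available) are all deliberate simplifications documented above.
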