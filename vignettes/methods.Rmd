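---
title: "Models and methods behind diabtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind diabtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diabtraj)
```

`diabtraj` is a pipeline for studying how diabetes-related health
parameters evolve around the diagnosis of incident type 2 diabetes (T2D)
in a three-exam longitudinal cohort, stratified by the novel diabetes
subtypes. This vignette documents the statistical models, the defaults and
why they were chosen, the numerical edge cases, and the limits of what the
synthetic-data checks can show.

## Subtype classification

GADA-positive individuals are assigned to SAID outright; everyone else is
assigned by the nearest-centroid rule in standardized feature space. For a
feature vector $x$ (age at onset, BMI, a glycemic measure, HOMA2-B,
HOMA2-IR), frozen training means $\mu$ and SDs $\sigma$, and centroids
$c_k$,

$$\text{subtype}(x) = \arg\min_k \left\lVert \frac{x - \mu}{\sigma} - c_k
\right\rVert_2, \qquad k \in \{\text{SIDD, SIRD, MOD, MARD}\}.$$

Three variants differ only in the glycemic feature: `hba1c` (the original
scheme), `fpg` (fasting plasma glucose replaces HbA1c, for cohorts where
HbA1c was not measured at every exam), and `glycemia_free` (no glycemic
feature). FPG enters in mg/dL, taken at the classification exam, and is
standardized with its own training mean/SD; no pseudo-HbA1c conversion is
attempted. Insulin-based HOMA indices (not C-peptide-based) are the
accepted inputs.

Published centroids can be loaded from a YAML file (`load_centroids()`);
none are bundled, because no reference values are publicly printed for the
FPG variant. When no file is supplied, `fit_centroids()` fits k-means
(k = 4, Euclidean, best of 25 seeded restarts) to the eligible cases and
labels the four centers by the subtype definitions: lowest HOMA2-B →
SIDD, then highest HOMA2-IR → SIRD, then highest BMI → MOD, remainder →
MARD. This labelling rule is this package's own device — the source scheme
assigns to *predefined* centroids and never fits clusters — but it follows
directly from the clinical characterisations of the subtypes.

Numerical choices: exact distance ties are broken in the fixed order
SIDD < SIRD < MOD < MARD, so results cannot be platform-dependent;
zero-variance training features and fewer than four complete rows are
fitting errors; missing features for a GADA-negative row are
classification errors, never silently imputed.

## HOMA indices and units

The HOMA equations are written for glucose in mmol/L and insulin in
µU/mL. Cohort glucose is in mg/dL, converted with the molar mass of
glucose, 18.016 mg/dL per mmol/L (fixed, documented and tested); fasting
insulin in mIE/L is numerically identical to µU/mL. The internal default
is the HOMA1 closed forms

$$\text{HOMA-IR} = \frac{G \cdot I}{22.5}, \qquad
  \text{HOMA-B} = \frac{20\,I}{G - 3.5},$$

because the HOMA2 structural model exists only as a closed-source
calculator. Files that already carry calculator-derived `homa_b`/`homa_ir`
columns are used as-is (`add_homa()` keeps them unless told to overwrite);
`method = "homa2_model"` is a reserved plug-in slot that currently raises
a not-implemented error rather than pretending to be HOMA2. Rows with
glucose at or below 3.5 mmol/L (where HOMA-B is undefined) or
non-positive insulin are flagged `homa_valid = FALSE` with `NA` indices —
flagged, not clamped, since clamping would silently move points toward the
SIDD/SIRD centroids.

## Eligibility, exclusions, timeline

A participant-exam meets the T2D definition when FPG ≥ 126 mg/dL, 2-h
post-load glucose ≥ 200 mg/dL (both inclusive), or a registry diagnosis is
recorded. Family history of diabetes (FHD) is positive with at least one
first-degree or two second-degree affected relatives.

Incident cases must be diagnosed strictly after the baseline exam and at
most 5 years before an attended follow-up exam; the earliest such exam is
the *classification exam*. If a diagnosis fell within 5 years of both
follow-up exams (possible only under irregular attendance), the earlier
exam wins, deterministically. The exclusion cascade then removes, in
order and with full logging: participants missing any classification
variable at the classification exam; hypoglycemia (FPG < 70 mg/dL at the
classification exam); and outliers more than 5 SDs from an outcome's
mean.

Two choices in the outlier rule are this package's own. First, the
reference mean/SD are computed per exam cycle over the current analysis
sample *excluding the evaluated individual* (leave-one-out): with the
candidate included, a single extreme value can never exceed
$(n-1)/\sqrt{n}$ SDs, so the rule would be a no-op in small samples; the
jackknife version behaves identically at large $n$ and remains effective
at any $n$. Second, the boundary is strict (greater than 5 SD), with a
$10^{-8}$ relative guard so a value at exactly 5 SD is never flagged
through floating-point rounding.

Timeline alignment re-anchors each case at its classification exam:
relative labels `20y-pre`, `10y-pre`, `classification`, `10y-post` and
`relative_time` in years from that exam. Cases classified at the second
exam contribute `10y-pre / classification / 10y-post`; cases classified
at the third contribute `20y-pre / 10y-pre / classification`. Controls
keep their calendar schedule; anchoring them at the second exam is a
package convention so both groups share one plotted axis. The control
group can optionally be restricted to FHD-free participants
(`exclude_fhd`), a sensitivity toggle rather than a default, because
published cohort tables show substantial FHD among controls while some
study summaries describe controls as FHD-free; the package takes no
position and exposes both.

## Trajectory models

For each outcome $y_{ij}$ (participant $i$, observation $j$):

$$y_{ij} = \beta_0 + \beta_{g(i)} + \beta_{t(ij)} + \beta_{g(i) \times t(ij)}
  + \gamma^\top z_{ij} + b_i + \varepsilon_{ij},
  \quad b_i \sim N(0, \tau^2), \; \varepsilon_{ij} \sim N(0, \sigma^2),$$

fitted by REML with `lme4::lmer`. The random structure is a participant
random intercept only: with at most three observations per person, random
slopes are weakly identified, so they are deliberately not the default.
Relative time $t$ is a categorical factor over the four labels by default
(matching the discrete exam-aligned means usually plotted); continuous
years are available by `time_coding = "continuous"`.

Adjustment sets: *model 1* adds examination cycle, age and sex; *model 2*
adds education, smoking, FHD, physical activity, BMI (except when BMI is
the outcome) and blood-pressure medication (only for SBP/DBP outcomes).
The examination cycle enters as a separate categorical term from relative
time: it absorbs assay and platform drift between exams (cohorts of this
design often changed glucose assays at later exams). Age enters as age at
the observation (time-varying); baseline age would be collinear with exam
cycle. An `adjustment = "none"` level exists for simulation studies where
the group-by-time cell means must equal known generator values.

Degenerate inputs are handled explicitly: categorical covariates observed
at fewer than two levels are dropped with a recorded warning;
fixed-effect columns aliased because a group-by-time cell is empty (the
controls never contribute a `20y-pre` exam) are dropped and recorded,
while any other rank deficiency is an error naming the aliased terms;
optimizer non-convergence is flagged on the result, not thrown; a single
observed time level reduces the mean structure to groups only.

Estimated marginal means (EMMs) are computed on the `emmeans` reference
grid — continuous covariates at their sample means, categorical covariates
averaged over observed frequencies — with delta-method SEs and asymptotic
(normal) degrees of freedom; with three observations per participant and
hundreds of participants, the normal approximation is adequate and much
faster than Satterthwaite, which `emmeans` can still provide if requested
from the stored model. Pairwise subtype contrasts are reported both raw
and multiplicity-adjusted; the default adjustment is Tukey (the natural
family-wise method for all-pairs comparisons), with Bonferroni and none as
alternatives, and the method used is always recorded in the output.
Because the published analyses do not state whether comparisons were made
at each time point or pooled over time, both are implemented
(`by_time`); pooled contrasts drop groups with any empty cell from the
average, so the per-time-point version is the pipeline default.

Descriptive baseline tables summarise continuous biomarkers as
median [Q1, Q3] (mean ± SD for variables declared normal) and categorical
variables as n (%). Two-group comparisons use Mann–Whitney U (or
Student/Welch t chosen by an F-test of equal variances, for
normal-declared variables) and chi-square, switching to Fisher's exact
test when any expected cell count falls below 5. Across the four
subtypes, Kruskal–Wallis with Dunn's rank-based post-hoc test (implemented
here with the standard tie-corrected large-sample z statistic) and ANOVA
with Dunnett contrasts against controls are available.

## The synthetic cohort generator

The generator emulates the design the analysis assumes: three exam cycles
at calendar offsets 0/10/20 years, baseline ages 35–56, FHD-enriched
sampling, incident diagnoses between exams with the classification exam at
most 5 years after diagnosis, and monotone dropout. Each case's latent
outcome trajectory is piecewise linear in time relative to the
classification exam, with an intercept at 20 years pre, one slope before
and one after the breakpoint — the simplest structure exercising a
slope change at diagnosis. Controls follow a single linear calendar-time
trend. One shared random intercept per participant per outcome and i.i.d.
Gaussian exam-level noise match the default analysis model, keeping
parameter recovery identifiable at small n.

Defaults follow the study design the package targets where that design is
published: subtype sizes 20/33/29/133 with 2531 controls, FHD prevalence
81.4% in cases and 56.3% in controls, 63% of cases classified at the
third exam, diagnosis lags uniform on [0, 5] years. Quantities no cohort
publication states — per-outcome residual and between-person SDs, slope
values, the 20% per-exam dropout — were chosen once as values a cohort
epidemiologist would call realistic (e.g. FPG residual SD 8 mg/dL against
a control mean near 83 mg/dL; BMI between-person SD 3 kg/m²) and are
free parameters of `simulation_config()`, not estimates of any real
cohort. The default subtype profiles reproduce the qualitative orderings
reported for such cohorts — SIDD highest FPG with the steepest beta-cell
decline, SIRD highest insulin and HOMA2-IR, MOD highest BMI, controls
flattest — and are illustrative only.

Two generator conventions matter for interpretation. Diagnosis assignment
is explicit (a drawn lag), not triggered by simulated glucose crossing
126 mg/dL, so subtype sample sizes are controlled exactly; a
`threshold` mode exists to stress-test ascertainment. And cases always
attend exams up to their classification exam (dropout applies after it),
which is what makes the configured sizes exact.

What passing tests on this generator do **not** show about real data: the
generator has no GADA-positive cases, no medication or mortality
processes, linear latent trends with a single breakpoint, Gaussian noise,
and missingness completely at random given the monotone structure. Perfect
cluster recovery on well-separated noise-free cohorts validates the
classifier's mechanics, not its accuracy on real, overlapping subtype
distributions — published replication accuracies around 88–91% reflect
that real overlap.

## Simulation-based calibration

Two properties are checked by simulation at fixed problem sizes, chosen
to balance Monte-Carlo error against runtime: 200 cohorts of 400 cases
(four subtypes of 100) for Wald 95% interval coverage of the
group-by-time interaction effects, expected to lie in [90%, 99%]; and 50
cohorts of 100 cases generated with zero between-person variance, where
the median estimated random-intercept-to-residual variance ratio must
fall below 1/10. Both use the unadjusted model so the generator's cell
means are the exact truth.

## Known limitations

- The HOMA2 structural model is not reimplemented; HOMA1 closed forms are
  a documented substitution and precomputed HOMA2 columns are preferred
  when available.
- Published trajectory curves from restricted cohort data are not
  reproducible here; the package reproduces the *method*, validated on
  synthetic cohorts.
- Complete-case analysis with logging is the only missing-data strategy;
  no imputation.
- Exclusions are applied once at cohort construction; post-classification
  exams are not re-screened for extreme values.
- The concordance metric is reported per variant pair without asserting
  which published figure corresponds to which pair, since the source
  description is ambiguous.
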