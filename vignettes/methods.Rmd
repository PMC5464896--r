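---
title: "Diffusion models, growth-rate prediction, and validation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion models, growth-rate prediction, and validation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwigrowth)
```

## The problem

Head and neck squamous cell carcinomas can progress quickly, and the
growth rate of the primary lesion bears directly on treatment priority.
Measuring growth directly requires two same-modality scans separated by
weeks; this package implements the non-invasive alternative: predict the
30-day growth rate from the diffusion microstructure parameters of a
single multi-b-value DWI examination, and provide everything needed to
build, validate and stress-test such a predictor.

The analysis operates on ROI-mean signal decay curves — one mean
intensity per b-value for a tumor region of interest — rather than
voxelwise maps, because ROI averaging gives the high SNR the multi-b
fits need. Image-domain concerns (registration, distortion, ROI
delineation) are upstream of this package; its inputs are plain tables.

## Signal models and units

Five models describe the decay of the ROI-mean signal $S(b)$ relative to
$S_0 = S(0)$:

* mono-exponential: $e^{-b \cdot ADC}$;
* bi-exponential (IVIM): $f e^{-b D^*} + (1-f) e^{-b D}$, separating a
  perfusion ("pseudo-diffusion") fraction $f$ with fast coefficient
  $D^*$ from true tissue diffusion $D$;
* tri-exponential: $f_1 e^{-b D_1} + f_2 e^{-b D_2} + f_3 e^{-b D_3}$
  with $f_1+f_2+f_3 = 1$ and $D_1 \ge D_2 \ge D_3$ — a perfusion-related
  compartment plus an intermediate compartment (associated with the
  extracellular extravascular space) and a slow compartment (associated
  with the cellular component);
* diffusion kurtosis: $\exp(-b D_k + \tfrac16 b^2 D_k^2 K)$;
* stretched exponential: $\exp(-(b \cdot DDC)^\alpha)$.

All diffusion coefficients are stored and reported in $10^{-3}$ mm²/s,
the convention in which soft-tissue values are order 1 and directly
comparable across publications; the factor of $10^{-3}$ is applied only
inside the forward evaluation where $b$ (s/mm²) multiplies a
coefficient. The packaged prediction equation's coefficients (−43.3,
−91.2) follow the same convention (a published form quoted per mm²/s
carries the corresponding $10^3$ factors).

## The acquisition scheme

The default `b_scheme()` is the 12-b-value protocol b = 0, 10, 20, 30,
50, 80, 100, 200, 400, 800, 1000, 2000 s/mm² with 1 signal average below
b = 100, 2 for 200–800 and 3 at 1000–2000. The low-b points carry the
perfusion information for the bi-/tri-exponential fits; mono/SEM/DKI
target tissue diffusion only and therefore use the six-b subset
{0, 200, 400, 800, 1000, 2000} s/mm², excluding the perfusion-sensitive
points.

## Fitting procedures

The bi- and tri-exponential models are fitted with the segmented
(stepwise) strategy that is standard for IVIM-type problems, because a
fully free multi-exponential fit on 12 points is poorly conditioned:

* **bi-exponential, two steps** — (1) a log-linear mono-exponential fit
  on b > 200 s/mm² (strictly greater, i.e. {400, 800, 1000, 2000})
  estimates D; (2) f and D* are fitted over all b-values with D fixed
  and $S_0$ pinned to the measured b = 0 signal.
* **tri-exponential, three steps** — (1) a log-linear mono fit on
  b ∈ {800, 1000, 2000} estimates $D_3$; (2) a two-component fit on
  b ≥ 200 (inclusive) with $D_3$ fixed estimates $D_2$; (3) $D_1$ and
  the fractions are fitted over all b with $D_2, D_3$ fixed,
  $f_3 = 1 - f_1 - f_2$ and $S_0$ pinned.

The step-1 mono fits float an amplitude (log-linear regression with
intercept) rather than pinning it to $S_0$: the high-b asymptote of a
multi-exponential signal extrapolates to $(1-f)S_0$, not $S_0$, and the
free intercept is what makes the step exact on noiseless
single-compartment input. The intercept gap also supplies the starting
value for the perfusion fraction.

Two documented biases of the stepwise estimators matter when the
procedure is interpreted quantitatively. The $D_3$ window (b ≥ 800)
still contains intermediate-compartment signal, so stepwise $D_3$ is
biased upward — about +9% at the reference cohort means, bounded below
15% across the tested range. That bias then propagates into the step-2
$D_2$. For this reason `fit_triexp_joint()` (and `fit_biexp_joint()`)
refine all free parameters simultaneously under the fraction-sum
constraint, initialized from the stepwise output; on noiseless
model-true curves the joint fits recover the generating parameters to
machine precision, and `fit_all_models()` performs stepwise-then-joint
by default while keeping the stepwise results in its `stepwise` element.

The optimizer is bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with box bounds f ∈ [0, 1], diffusion
coefficients ∈ [10⁻³, 500] (in 10⁻³ mm²/s), α ∈ (0, 1], K ∈ [0, 3];
cost and parameter tolerances 10⁻¹⁰, at most 5000 residual evaluations.
Starting values: coefficients from log-linear fits, D* at 20, α at 0.8,
K at 0.7. The fraction-sum constraint is handled by parameterizing two
free fractions; compartment ordering is restored by relabeling if the
optimizer exchanges components (the model is invariant under
permutation). Curves with fewer distinct b-values than a model needs are
rejected with explicit errors rather than silently under-determined
fits.

### Identifiability limits

When two compartments have nearly equal coefficients ($D_2 \approx
D_3$), the tri-exponential model is locally non-identifiable: a flat
direction appears in the least-squares surface and the fitted
$(f_2, D_2, f_3, D_3)$ can land anywhere on it while reproducing the
curve to within tolerance. In cohort simulations with the reference
distributions, roughly 5–10% of patients fall in this regime. This is a
property of the model, not the optimizer; downstream analyses that use
fitted $D_2$ therefore carry a small errors-in-variables component, and
the package's end-to-end tests assert coefficient recovery at the few-%
level rather than machine precision when parameters come from re-fitted
curves.

## Growth rate

From two same-modality scans, the directly measured growth rate solves
$Size_{post} = Size_{pre} \cdot (Growth/100)^{duration/30}$: the
projected 30-day size ratio scaled so no-growth = 100. It is invariant
to the size unit and exactly inverted by `project_size()`. Durations are
plain day differences between scan dates. The packaged HNSCC equation

$$\widehat{Growth} = 227.5 - 43.3\, D_2 - 91.2\, D_3$$

predicts this rate from the tri-exponential intermediate and slow
coefficients; both slopes are negative — denser, faster-growing tumors
restrict water diffusion in both the extracellular space and the
cellular compartment.

## Statistical pipeline

The discovery analysis mirrors the screen-then-exclude-then-fit recipe:

1. **Univariate screen** — simple regression of the growth rate on each
   encoded predictor (demographics, staging, lesion size, all 14
   diffusion parameters), reporting the signed Pearson r and slope-t
   p-value, flagged at 0.05. Categorical predictors are coded binary
   (sex, primary-site group, smoking) or ordinal (T-stage 1–4 with
   T4a/T4b merged, N-stage 0–3, alcohol use 0/1/2); correlations on
   binary codes are point-biserial. No multiplicity correction is
   applied, matching the screening character of the step.
2. **VIF exclusion** — variance inflation factors $1/(1-R_j^2)$ over the
   significant candidates; the largest VIF above 10 is removed
   iteratively (ties broken by the weaker outcome correlation; perfect
   collinearity yields an infinite VIF and removal, never a division
   failure). The procedure is idempotent. The intermediate-diffusion
   quartet ADC, D, DDC, $D_k$ indexes nearly the same tissue property as
   $D_2$ and is what this step typically removes.
3. **Multivariate regression** — ordinary least squares on the retained
   set with backward elimination of non-significant coefficients, so the
   final equation keeps only significant terms; raw and standardized
   partial coefficients (raw × SD(x)/SD(y)) and the multiple correlation
   (r between fitted and observed) are reported.

Validation applies the frozen equation to held-out patients and reports
the Pearson r and ICC(2,1); `crossvalidate()` repeats the whole
discovery analysis per training fold (a 55-patient cohort with k = 5
gives the 44/11 design) and scores each test fold. The ICC form used
everywhere — inter-rater agreement and predicted-vs-measured agreement —
is ICC(2,1): two-way random effects, absolute agreement, single
measures, computed from ANOVA mean squares. Agreement and correlation
strengths are labeled on the conventional bands poor/fair/moderate/good/
excellent with half-open boundaries [0, 0.2), [0.2, 0.41), [0.41, 0.61),
[0.61, 0.81), [0.81, 1], closing the gaps in the printed scale.

Group comparisons use the Mann–Whitney U test: full enumeration of the
rank-sum distribution (midranks, so ties are exact) when both groups
have ≤ 8 observations, otherwise the tie-corrected normal approximation
without continuity correction.

## Survival analysis

Patients are dichotomized at the ROC cutoff closest to the upper-left
corner, computed against end-of-follow-up status (non-survivor for OS,
progression for PFS). Candidate thresholds are the midpoints between
adjacent sorted unique scores; when several achieve the minimal corner
distance the more sensitive one wins (treatment-priority rationale).
Because the candidate set is midpoint-based, cutoffs on other data are
reproducible in spirit, not digit-for-digit. Kaplan–Meier curves
(product-limit, right censoring) and the two-group log-rank test
(hypergeometric variance, 1 df, no continuity correction) compare the
low- and high-growth groups; a cohort with no events yields an
explicitly undefined test, not a crash.

## The synthetic cohort generator

`simulate_cohort()` produces cohorts with the statistical structure the
pipeline assumes, so every stage is testable without any patient data:

* The six coefficients (ADC, D, DDC, $D_k$, $D_2$, $D_3$) are drawn from
  a truncated correlated normal anchored to the published cohort means
  and SDs. The cross-correlations default to a block of 0.9 among
  {ADC, D, DDC, $D_k$, $D_2$} — emulating the interchangeable
  intermediate-diffusion parameters that the VIF step exists to remove —
  and 0.45 between $D_3$ and each block member. The true correlation
  matrix of any real cohort is unpublished; these are calibration
  choices, validated only in the sense that the pipeline behaves as the
  method expects (positive definiteness is checked and violations error
  with the offending pair).
* The true growth rate is the packaged equation evaluated at the drawn
  $(D_2, D_3)$ plus Gaussian noise whose SD is calibrated analytically
  so the population correlation between equation prediction and realized
  rate hits a target (default 0.74). Two-timepoint sizes then follow
  from `project_size()` with truncated-normal durations (mean 34.2, SD
  4.15 days, range 25–43) and first-scan sizes anchored to the reference
  distribution.
* Signal curves are synthesized per patient from the drawn
  tri-exponential parameters. Noise is Rician by default (magnitude MR
  data): the modulus of the complex signal with independent Gaussian
  components of SD $\sigma_b = (S_0/\mathrm{SNR})/\sqrt{NSA_b}$, so the
  averaging tiers of the acquisition reduce noise as acquired data
  would. Gaussian and noiseless modes exist for oracle tests. The
  default b = 0 SNR of 100 reflects ROI-mean (not voxelwise) intensity
  averaging; the reference study measured SNR but its values are not
  reproducible from the publication.
* Survival outcomes are exponential event times with log-hazard affine
  in the standardized growth rate and uniform administrative censoring
  within the follow-up windows (8–42 months OS-like, 4–42 PFS-like);
  link 0 gives a calibrated null.

What the generator does **not** emulate: image-domain effects
(partial volume, necrosis exclusion, ROI delineation variability),
non-Gaussian parameter distributions, informative censoring, or any
relationship between demographics and growth. Passing tests on this
generator therefore demonstrate the correctness and calibration of the
computational pipeline, not clinical performance on real patients.

## Numerical and testing choices

Problem sizes in the test-suite were chosen to exercise each claim at
desk scale: round-trip fits run on single curves; regression recovery
uses 200 cohorts of n = 40; null calibration of the log-rank test and
the univariate screen uses 2000 simulations; cross-validation design
checks use one 55-patient cohort. All generators are bit-reproducible
given a seed, and every stochastic split takes a mandatory seed
argument. Oracles are independent of the paths they check: full
enumeration for the Mann–Whitney p, explicit ANOVA sums for ICC(2,1),
brute-force threshold scans for the ROC cutoff, hand product-limit and
observed-minus-expected computations for Kaplan–Meier and log-rank, and
closed-form slopes for two-point mono-exponential fits.

## Known limitations

* The stepwise tri-exponential $D_3$/$D_2$ estimates carry the
  deterministic biases described above; joint refinement removes them on
  model-true input but inherits the identifiability limit when
  compartments coincide.
* The DKI signal expression is monotone only up to
  $b \approx 3/(D_k K)$; for fitted parameter ranges this lies beyond
  2000 s/mm², inside the acquisition range the model is used.
* ICC(2,1) is reported as the single agreement form throughout; studies
  using consistency or average-measures forms will differ.
* The ROC cutoff convention (midpoints) can differ from conventions
  that evaluate at observed values; sensitivity/specificity at the
  chosen cutoff are identical either way on the data that chose it.
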