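---
title: "Methods: digital-twin cohorts and Monte Carlo scenario simulation for USVT anticoagulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital-twin cohorts and Monte Carlo scenario simulation for USVT anticoagulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`usvtwin` studies a question that cannot be settled by trials: how do
direct oral anticoagulants (DOACs) compare with vitamin K antagonists
(VKAs) in unusual-site venous thrombosis (USVT — splanchnic, upper-
extremity and cerebral venous territories), a rare condition where the
available real-world cohorts hold on the order of 90 patients? The package
chains five statistical components — a calibrated cohort emulator, a
conditional generative model, fidelity diagnostics, propensity-conditioned
outcome models and a nested Monte Carlo engine — and this vignette records
the model behind each stage, the defaults and the reasoning for them, and
the limits of what such a pipeline can show.

## The patient data model

A cohort is a validated data frame over a fixed schema (`usvt_schema()`):
demographics (age in years, sex), thrombosis site (`SVT`/`UEDVT`/`CVT`),
treatment arm and DOAC agent, thirteen binary comorbidity flags plus
thrombophilia and antiplatelet co-medication, admission labs (hemoglobin
g/dL, platelets 10⁹/L, D-dimer ng/mL), VKA time-in-therapeutic-range (TTR,
percent), follow-up in months, and four outcomes: complete recanalization
(three levels — `complete`, `not_complete`, and an explicit `missing` level
for patients without follow-up imaging), recurrence, major bleeding and
death. Structural invariants are enforced at construction: TTR is defined
iff the patient is on a VKA, the agent iff on a DOAC, age ≥ 18, follow-up
≥ 0. Missingness is otherwise prohibited — the pipeline is complete-case
by design, with recanalization's imaging availability modeled explicitly
rather than imputed.

Descriptive ("Table 1 style") summaries follow the conventions of the
clinical literature: continuous variables as mean ± SD or median (IQR)
according to a Shapiro–Wilk test at α = 0.05, compared by t-test or
Mann–Whitney; categorical variables as counts (one-decimal percent),
compared by chi-square, or Fisher's exact test whenever any expected cell
count falls below five. The normality test is applied to the pooled sample
rather than per arm — per-arm testing could select different summary
formats for the two columns of the same row; the choice is exposed through
`shapiro_alpha` should per-arm behaviour ever be wanted.

## The source-cohort emulator

No patient-level USVT registry data are public, so the pipeline starts
from an emulator (`source_config()` / `sample_cohort()`) whose defaults
are calibrated to the published cohort's margins: n = 90, P(VKA) = 65/90,
arm-conditional site mixes, arm-conditional comorbidity prevalences, and
arm-conditional outcome rates (complete recanalization among imaged
patients 0.36/0.40, recurrence 0.077/0.080, major bleeding 0.108/0.080,
death 0.60/0.20 for VKA/DOAC). Within an arm, covariates are independent;
the arm itself is the only dependency encoded, because arm-specific
prevalences are the only joint information the published tables carry.
Distributional families were chosen for positive support consistent with
the printed summaries:

* age — normal per arm (68.9 ± 17.2 / 63.9 ± 18.6), rejection-sampled
  into [18, 100];
* labs and follow-up — log-normal per arm, with `meanlog = log(median)`
  and `sdlog = (log q3 − log q1) / (2 Φ⁻¹(0.75))`;
* TTR — Beta on [0, 100] with shape parameters solved numerically so the
  quartiles match the printed 51.4 / 60.9 / 70.8;
* imaging availability — Bernoulli per arm (25/65 VKA, 15/25 DOAC).

The INR-series simulator (`simulate_inr_series()`) exists to give the TTR
field a generative backing: a mean-reverting AR(1) walk around INR 2.5
(persistence 0.8) whose stationary SD is set by
`σ = 0.5 / Φ⁻¹((1 + f)/2)` so that a fraction `f` of measurements falls in
the therapeutic band [2, 3]; with strong autocorrelation the
linearly-interpolated fraction of *time* in band tracks the fraction of
*points* in band, and the Monte Carlo contract (mean TTR within ±5 points
of the target over 200 series) holds. `rosendaal_ttr()` computes the
standard Rosendaal measure exactly — each linear segment's in-band time is
obtained from the analytic crossing points, not a grid — and is tested
against a fine-grid integration oracle.

What the emulator does **not** emulate: within-arm covariate correlations
(e.g. cancer–age), longitudinal trajectories, and site-specific outcome
differences. Consequently, a pipeline that passes its tests on emulated
data is validated for its *statistical machinery*; nothing here certifies
performance on a real registry with richer dependence.

## The DAG-informed conditional GAN

The generative model is authored in base R matrix code (the environment
has no deep-learning framework, and the generator is the methodological
core of the package, not a step to outsource).

**Architecture.** Variables split into a conditioning set (default: site,
treatment, age, sex, active cancer) and generated variables. Each generated
variable owns a small MLP "head" (one tanh hidden layer of 32 units by
default) that maps a shared 8-dimensional latent Gaussian vector plus the
encoded values of its *context* to the variable's encoding: a linear unit
for z-scored continuous variables, a sigmoid for binary flags, a softmax
over one-hot levels for categoricals. The context is the variable's parent
set in a clinical DAG (`default_dag()`: the four covariates feed treatment;
all five feed each outcome); variables outside the DAG see the full
conditioning set. Generation proceeds in topological order, outcomes are
terminal heads, and conditioning on an outcome is a contract error — the
causal reading is thus enforced by the wiring itself, which is testable
(`head_context()`). One shared discriminator (tanh MLP, 32 units) scores
the concatenated record.

**Structural missingness.** TTR and DOAC-agent encodings are zeroed for
the arm where they are undefined, on both the real and generated side, so
the discriminator cannot exploit them; at decode time they are restored to
`NA` deterministically from the treatment value.

**Training.** Alternating single-step Adam updates (β₁ = 0.5, learning
rates 10⁻³) with the binary cross-entropy objective: one discriminator
step per epoch on a 32-row minibatch (real discrete encodings smoothed by
ε = 0.05), one full-table generator step. On 90-row tables a purely
adversarial objective is unstable, so the generator loss adds a
**conditional moment-matching penalty** (weight 10): squared error between
generated and training means of (i) every encoded column, (ii) every
column's interaction with each conditioning one-hot — which pins the
arm-conditional and site-conditional rates — and (iii) the second moments
of continuous encodings, which preserves variances. The adversarial term
is then free to shape what the moments do not constrain. Defaults of 2000
epochs train in well under a minute at this scale.

**Convergence** is declared when a trailing 100-epoch moving average of
both losses oscillates by at most 5% (relative range over the final
window); failure is flagged and warned about, never silent, and the
post-hoc arbiter of usability is always the fidelity report, not the loss
curve.

**Generation.** 1:1 twin cohorts reuse the training rows' conditioning
values — this makes the conditioned marginals match the source exactly,
which is the point of conditional twinning; for other sizes the
conditioning rows are resampled. Categorical draws use
softmax-with-temperature; the default temperature is 1 because any
sharpening (T < 1) would bias binary prevalences toward the extremes and
hence corrupt exactly the marginals the fidelity module audits. Generated
continuous values are clipped to the training range widened by 5% (domain
closure). Replicas (`replicate_twins()`) use seeds `seed_base + i`, so
every replica is independently reproducible.

## Fidelity metrics

The absolute standardized mean difference uses the pooled-variance
convention, `|m₁ − m₂| / sqrt((v₁ + v₂)/2)`, with `p(1−p)` variances for
binary variables and the mean of per-level dummy ASMDs for multi-level
categoricals (chosen over a Mahalanobis variant for interpretability).
MASMD is their mean (SD reported with the sample convention); the
thresholds are < 0.10 (target) and ≤ 0.20 (acceptable). The squared MMD is
the unbiased U-statistic with a Gaussian kernel and median-heuristic
bandwidth, with significance from a 200-permutation null; KS tests cover
continuous variables only (heavily tied data invalidate KS, so categorical
marginals are compared by total-variation distance, reported but not
gated). Spearman matrices use a fixed documented encoding: flags as 0/1,
site as the ordinal SVT = 0 < UEDVT = 1 < CVT = 2, recanalization
complete = 1 / not-complete = 0 with missing as `NA`.

A sampling caveat that matters when reading the correlation-similarity
fraction: comparing two 90-row cohorts means comparing two rank
correlations each estimated with SE ≈ 0.107, so even a *perfect* generator
yields |Δρ| < 0.1 for only about half of all pairs. The package therefore
reports the fraction without gating on it.

## Propensity conditioning

The propensity model is a maximum-likelihood logistic regression of DOAC
assignment on age, sex, site (two dummies against the SVT reference, the
modal category) and active cancer; constant columns are dropped, and
separation triggers a Firth bias-reduced refit (flagged). Matching is 1:1
greedy nearest-neighbour without replacement on the logit-score scale with
a caliper of 0.2 SD — the standard observational-methods default, exposed
in configuration up to caliper ∞. The smaller arm is visited in a seeded
random order over its score ranks, which makes the pair multiset both
deterministic under the seed and invariant to permutations of the input
rows. Balance is reported as per-variable ASMDs over the four matching
covariates with the same 0.10/0.20 thresholds. The matched cohort size is
reported, never asserted: with ~25 DOAC twins it is bounded by the smaller
arm, and at that size *expected* ASMDs under perfect balance are already
≈ 0.2, so small-cohort balance numbers should be read as noisy.

## Outcome models

Each endpoint — complete recanalization (coded complete = 1 vs
not-complete = 0, fit on imaged records and then applied to the whole
cohort; the missingness is assumed ignorable given the predictors, a
documented assumption), recurrence, major bleeding — gets a logistic
model on the default predictor set {treatment, site, active cancer}, with
age, sex and a binary TTR "good control" stratum (TTR ≥ 70, VKA rows only)
as optional toggles. The TTR stratum exists so the perfect-control
scenario has a lever to pull. Two numerical safeguards address the sparse
CVT cell (two patients in ninety): an optional ridge penalty on the site
dummies (default 0.5 in the pipeline), and a Firth fallback whenever a fit
separates (a zero-event arm in a small matched cohort is common).
Treatment-specific rates come from counterfactual marginal
standardization — every record scored under both arms, rates averaged —
with percentile-bootstrap CIs over records (1000 resamples; the CI method
is a package choice, labeled as such). Calibration is assessed by Brier
scores and equal-frequency calibration bins.

## The two-layer Monte Carlo engine

Layer 1 builds a scenario case-mix of M rows from the conditioned cohort
by resampling *within strata* of the perturbed variable, so the target
marginal is hit in expectation while all within-stratum joint structure is
preserved — rows are resampled, never edited. The four perturbations are:
70% DOAC / 30% VKA; cancer prevalence × 1.5; CVT raised to 40%; and
perfect VKA control, the one deterministic edit (VKA rows reassigned to
the `ttr_control = 1` stratum), since reassignment is the stated meaning
of that scenario. An empty required stratum is a scenario-infeasibility
error naming the stratum — a 90-patient cohort can genuinely lack CVT
rows. Layer 2 draws, per record and endpoint, a Bernoulli outcome with
the model probability and averages within arms. Both layers are redrawn
each iteration.

Defaults: R = 500 iterations per scenario; M = 4000. M is not externally
fixed anywhere, so it was calibrated from first principles: with a roughly
1:1 matched case-mix, M = 4000 gives per-iteration binomial SDs of ≈ 1.1
percentage points for a 40% endpoint, hence empirical 95% CI half-widths
of ≈ 2 points, the scale on which such simulations are usually reported.
Reported diagnostics per scenario × endpoint × arm: mean rate, empirical
2.5/97.5-percentile CI, Monte Carlo standard error (absolute and as % of
the mean; target < 5%), coefficient of variation (target < 10%).
Directionality preservation is the fraction of iterations in which
sign(DOAC − VKA) matches the reference sign from the observed cohort; ties
count as non-preserving (conservative). For directionality at small true
differences, M = 4000 is not always enough — a 1.5-point difference needs
M ≈ 10⁴ before the per-iteration sign stabilizes at the 95% level — so
analyses that gate on directionality run at M = 10000. The sensitivity
suite reruns a scenario at R ∈ {100, 250, 500, 1000} and under a simple
weighted-resampling alternative to the stratified scheme; both estimate
the same marginal, so deviations beyond a few combined MCSEs indicate a
bug, not a finding.

Seeding uses one documented ladder (`derive_seed()`): master seed →
per-scenario seed → per-iteration seed (and analogous chains for pipeline
stages and replicas), all below 2³¹; the pipeline manifest records every
seed, and reruns are byte-identical.

## Design choices made where the design was open

* **DAG integration.** How a DAG "constrains" a conditional GAN is
  underdetermined; the package realizes it architecturally — topological
  generation order, per-head parent-only inputs, terminal outcome heads —
  because that makes the constraint a structural property that a test can
  inspect, rather than a soft regularizer whose effect is unverifiable.
* **Moment-matching penalty.** Added to make 90-row adversarial training
  reproducible across seeds; it is a method-of-moments anchor on exactly
  the quantities the fidelity module audits, and the fidelity report stays
  the independent referee.
* **Pooled Shapiro–Wilk**, **percentile-bootstrap CIs**, **caliper 0.2 SD**,
  **ridge 0.5 on site dummies**, **TTR ≥ 70 as "good control"**: each is
  the field-standard default for its step, exposed in configuration.
* **Problem sizes.** The test suite trains reduced configurations
  (150–600 epochs) for plumbing tests and the full 2000-epoch, 10-replica
  configuration in the end-to-end validation; simulation checks run at
  R ∈ {100, …, 500} and M ∈ {500, …, 10000} as noted above.

## Known limitations

* Everything downstream of `sample_cohort()` inherits the emulator's
  independence assumptions; real registries have within-arm dependence the
  twins are never asked to reproduce here.
* A 90-record training table bounds what any generator can learn: twin
  outcome rates carry binomial noise of several percentage points per arm,
  and a ~20-pair matched cohort carries more. Pipeline-level treatment
  differences at this scale are sign-stable only when the underlying
  difference is large; small printed differences (±1–3 points) are not
  recoverable from a single 90-patient realisation, and the package makes
  no claim to the contrary.
* The GAN provides no privacy guarantees and no longitudinal structure;
  mortality is summarized descriptively but never modeled (it is not an
  anticoagulation-effect endpoint here); no time-to-event or
  competing-risk machinery is included by design.
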