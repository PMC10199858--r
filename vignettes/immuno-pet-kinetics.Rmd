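---
title: "Kinetic quantification and cohort simulation for 89Zr immuno-PET dose escalation"
author: "ImmunoPatlak"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic quantification and cohort simulation for 89Zr immuno-PET dose escalation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ImmunoPatlak)
```

# The problem

Zirconium-89 immuno-PET images the whole-body distribution of a radiolabeled
monoclonal antibody over days -- the time scale antibodies need to reach
their targets.  When the target is an immune checkpoint such as LAG-3,
expressed at low density on tumor-infiltrating immune cells, two questions
dominate: is the PET signal *quantifiable*, and is it *target-specific*?
The study design this package implements answers both with mass-dose
escalation: every patient is first imaged with a tracer-only antibody dose
(4 mg), then re-imaged after an unlabeled pre-dose that raises the total
mass dose to 44 mg or 604 mg.  If the uptake is target-mediated, the
unlabeled antibody occupies the target and the tracer signal collapses
toward a non-specific floor.

Two features of antibody PK make naive uptake measures misleading here.
First, clearance is dose-dependent (target-mediated drug disposition): the
4-mg dose clears faster than the saturating doses, so SUV -- which ignores
plasma availability -- confounds target effects with clearance effects.
The package therefore treats **tissue-to-plasma ratios** as the primary
uptake measure and SUV as a secondary output.  Second, ⁸⁹Zr is a
residualizing label: after binding and internalization the radiometal
stays trapped in the cell, so the signal accumulates irreversibly and is
well described by an irreversible compartment model, which is exactly the
regime of **Patlak graphical analysis**.

# Models

## Plasma disposition

Decay-corrected plasma concentration (in percent injected activity per
litre, %IA/L) follows a bi-exponential disposition model per mass-dose
arm,

$$C_p(t) = A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 s\, t},$$

with a fast distribution phase and a slow terminal phase whose rate
carries the dose dependence through the clearance scale $s$.  The terminal
rate of each arm is identified by a two-point log-linear solve through the
published mean plasma concentrations at 90 and 138 h (4 mg: 6.2 → 3.2;
44 mg: 11.9 → 10.0; 604 mg: 14.5 → 11.9 %IA/L), and the slow amplitude
anchors the curve at the 90-h mean.  The distribution phase is weakly
constrained by this design (first blood draw at 1 h), so it is fixed by
convention: $\lambda_1 = 0.5\,\mathrm{h^{-1}}$ and $C_p(0) = 33$ %IA/L,
i.e. the injected activity initially dilutes into roughly 3 L of plasma.
`plasmaModelForDose()` performs this calibration; the population-PK model
the study itself used is not re-estimated.

## Receptor occupancy

Occupancy of the target by antibody is a Hill function of the administered
mass dose, $occ(D) = D^h/(D^h + D_{50}^h)$, evaluated per cycle.  Making
occupancy a function of the *dose* rather than of the instantaneous plasma
concentration keeps the net irreversible uptake rate constant within a
cycle, which is precisely the Patlak assumption; the alternative -- a
time-varying occupancy -- would buy realism the data cannot constrain at
the cost of invalidating the estimator under study.  A hyperbolic model
($h = 1$) cannot reproduce the published spleen saturation triple (the
ratio equations force a negative $D_{50}$), so $h = 2$ is used.
`calibrateOccupancy()` fixes the non-saturable floor at the fully blocked
604-mg spleen value (0.67 uL g⁻¹ h⁻¹) and fits $D_{50}$ by least squares
against the three published spleen net-uptake rates (30.06, 2.91, 0.67
uL g⁻¹ h⁻¹), giving $D_{50} \approx 11.9$ mg.  The Hill form leaves a
small irreducible residual at 604 mg (fitted 0.68 vs 0.67): occupancy
never reaches exactly 1.  A corollary worth flagging: the calibrated model
implies roughly 10% self-occupancy by the 4-mg tracer dose itself; this is
a property of the calibration, not a claim of the original study.

## Tissue kinetics

Every region follows the irreversible two-tissue compartment model

$$\frac{dC_{rev}}{dt} = k_1 C_p - (k_2 + k_3) C_{rev}, \qquad
  \frac{dC_{trap}}{dt} = k_3 C_{rev},$$

with measured concentration $C_t = C_{rev} + C_{trap} + v_b C_p$.  The net
irreversible uptake rate is $K_i = 1000\,k_1 k_3/(k_2+k_3)$ in
uL g⁻¹ h⁻¹ (tissue density 1 g/mL).  Blocking acts through
`effectiveKi()`: $K_i^{eff}(D) = K_i^{ns} + K_i^{spec}(1 - occ(D))$, and
the simulator chooses the trapping rate so the model's implied $K_i$
equals $K_i^{eff}$ exactly.  For exponential-sum inputs the state
equations are solved in closed form; piecewise log-linear inputs are
propagated segment-by-segment analytically, so no numerical integrator
enters the simulator.

Organ defaults: the spleen anchors its maximal trapping rate at the
published receptor re-synthesis rate (~10% per hour, $k_3^{max} =
0.1\,\mathrm{h^{-1}}$) with $k_1$ chosen to reproduce the calibrated
specific uptake; the lungs are anchored at their low published
organ-to-plasma ratio with no saturable component; liver, kidneys, bone
marrow and bone are plausible synthetic defaults (no published reference
values are available for them) in which hepatobiliary
and renal handling and the bone affinity of the free radiometal appear as
non-saturable irreversible floors.

## The tumor population and its calibration

Lesions draw a latent infiltration score $u \sim U(0,1)$; the kinetic
scale $w = e^{\sigma_w \Phi^{-1}(u)}$ (log-normal, $\sigma_w = 1$) drives
the specific uptake $K_i^{spec} = w\,K_{i,med}^{spec}$ and, with exponent
$\gamma = 0.3$, the perfusion-linked quantities $k_1$ and $v_b$ --
infiltrated lesions are modestly better perfused.  Simulated LAG-3
immunohistochemistry is a binomial draw of positive cells (at least 100
cells scored) with success probability increasing in $u$, and the
expression simulator plants $u$ plus noise in the signature genes.

Calibration proceeds in two stages (`calibrateTumorModel()`).  Stage one
fits the median lesion's $(v_b, K_{i,med}^{spec}, D_{50}^{tum})$ by
deterministic least squares (log scale) so the noise-free model reproduces
the four published lesion-level ratio medians: 1.63 (90 h) and 2.70
(138 h) at 4 mg, 0.67 at 44 mg and 0.58 at 604 mg (138 h).  $k_1 = 0.06$
mL g⁻¹ h⁻¹, $k_2 = 0.2$ h⁻¹ and a small non-specific floor (0.1
uL g⁻¹ h⁻¹) are fixed at physiologic antibody values.  The tumor
half-saturation dose is deliberately separate from the spleen's:
intratumoral antibody penetration is limited (the binding-site barrier),
so lesions are allowed to need a higher administered dose for the same
local occupancy; the fit lands near 13 mg, close to the spleen value.

Two honest imperfections are worth recording rather than hiding.  First,
the four medians jointly over-determine this model family: extensive
multi-start searches (including free $k_1$, $k_2$, $v_b$, floors) bottom
out with ~5% residuals on the two cycle-1 points, the unconstrained
optimum being a degenerate fast-exchange limit.  The least-squares
compromise is kept and reported.  Second, the *sample median* of noisy,
right-skewed ratio data is biased upward: with 10% multiplicative
measurement noise (plasma denominators shared within a patient) the
seed-averaged sample medians sit ~3-6% above the noise-free medians.
Stage two therefore estimates this drift by Monte Carlo under the full
generative law and refits against drift-corrected targets, so that the
*simulated* cohort summaries -- not an idealized noise-free curve -- match
the published numbers as closely as the family allows.

## Patlak analysis

`patlakTransform()` maps tissue and input to
$x(t) = \int_0^t C_p\,d\tau / C_p(t)$ and $y(t) = C_t(t)/C_p(t)$ using the
input model's exact integral; `patlakFit()` runs ordinary least squares in
the fitting window and reports $K_i = 1000 b$, the intercept (reversible
distribution volume) and $R^2$.  The default window excludes the < 2 h
scan: with efflux around 0.2--1 h⁻¹ the reversible compartment has not
equilibrated there, and including it would bias the slope.  Negative
fitted slopes -- which honest noise produces at the non-specific floor --
are flagged, never clamped, so replicate statistics stay unbiased.  Input
functions are fitted in log space; with four or more samples both phases
are free (Levenberg--Marquardt, curve-peeling start), with fewer samples
the unidentifiable fast phase is fixed at configured defaults.  A
`fix_fast` option extends the fixed-fast-phase fit to denser schedules,
because with antibody sampling schedules a fully free bi-exponential pins
the terminal slope on the last two samples alone.  Tumor-lesion $K_i$
values are computed on simulations for completeness, but the study design
provides no no-expression baseline for tumors, so their clinical
interpretation is out of scope.

# Statistical conventions

Organs and plasma are summarized as mean ± SD, lesions as median with
interquartile range (linear-interpolation quantiles); plasma dose-arm
contrasts use one-way ANOVA with Tukey HSD, lesion contrasts use
Kruskal--Wallis with pairwise two-sided Wilcoxon rank-sum tests (exact
when the smaller group has ≤ 10 observations and no ties) under Bonferroni
correction -- the conventions of the emulated study.  Lesions are pooled
across patients as independent observations, matching the study's
lesion-level group sizes; a patient-clustered sensitivity mode
(per-patient means) is available because the independence assumption is
questionable with 2--5 lesions per patient.  Saturation is quantified as
the blocked fraction of the specific signal,
$1 - (K_i^D - K_i^{floor})/(K_i^{ref} - K_i^{floor})$, classified full at
≥ 0.95 and partial at ≥ 0.5.

The immune readout is deliberately minimal: a mean per-gene z-score over a
signature set.  It is a monotone surrogate for enrichment-style scores
(GSVA and deconvolution pipelines are published tools, not re-implemented
here) and is used only to reproduce, at simulation scale, the
correspondence between tracer uptake, infiltration and signature scores.
Patients are labelled immune-desert versus infiltrated by the ≥ 3.0
threshold on the 4-mg 138-h mean tumor-to-plasma ratio.

# What the simulator does and does not emulate

The generator reproduces the study design faithfully: 6 patients; cycle-1
scans at < 2, 90, 138 h and cycle-2 scans at 90, 138 h; blood at 1 h and
after every scan; 37 MBq and 4 mg of tracer; 3/3 assignment to the 44- and
604-mg arms (patient numbering follows the published per-patient table);
2--5 lesions per patient with log-normal volumes matching the published
mean and range; log-normal patient variability on plasma amplitudes
(mean-preserving, CV 0.45) and terminal clearance (σ = 0.15); organ-level
log-normal variability of the specific component (σ = 0.3); 10%
multiplicative measurement noise, truncated to keep concentrations
positive.  Observed plasma is stored as decay-corrected %IA/L
(well-counter convention) while observed regions are stored as raw Bq/mL
without decay correction, so the quantification pipeline genuinely
exercises decay correction and unit conversion.  Scan-time jitter (±1 h)
and a dropped 90-h blood sample are available but off by default:
determinism first.

It does not synthesize images (no voxels, no partial-volume effects, no
delineation), does not let dose-dependent clearance *emerge* from a
mechanistic TMDD model (it is parameterized per arm), treats the two
cycles as kinetically independent (residual cycle-1 activity at the
cycle-2 scans is ~2% of the cycle-2 signal after physical decay, and is
neglected), and models measurement error as a single multiplicative
Gaussian because the study reports none.  Passing tests on this generator
therefore demonstrate correctness of the estimators under the stated
model, not robustness to image-domain artefacts.

# Numerical choices and degenerate inputs

Closed-form exponential algebra is guarded near the confluent case
$k_2 + k_3 \to \lambda$ and at zero rates by series limits.  Lesion draws
are capped so the implied trapping never exceeds 95% of the delivery
limit $1000\,k_1$ (the model is undefined beyond it, and a draw past it
would otherwise abort a cohort roughly once per hundred seeds).  Degenerate
Patlak abscissa spread (< 1e-9 h), empty groups, all-identical ANOVA
inputs, zero plasma concentrations and non-positive fit inputs raise
explicit errors; zero-variance signature genes contribute zero with a
warning.  All randomness flows from the single configured seed through a
saved-and-restored RNG state, so cohorts are pure functions of
configuration and generation never disturbs the caller's RNG stream.

Problem sizes used by the shipped checks, chosen to keep the full suite in
tens of seconds while leaving Monte-Carlo error well below the tolerances
they probe: 50 seeded cohorts for calibration round-trips and dose-ordering
rates; 200 replicates per $K_i$ level for noise recovery; 600--1200
Monte-Carlo cohorts inside the drift-correction stage; an explicit-Euler
cross-check of the closed-form kinetics at a 0.001 h step (first-order
Euler at coarser steps is less accurate than the discrepancy bound being
verified).

The noise-recovery protocol merits one explicit design note: it uses the
arm's disposition model as the Patlak input (as the study did, whose input
was a population-PK prediction) with measurement noise on the tissue
curve, the low-background reference tissue ($v_b = 0.1$, $k_1 = 0.05$,
$k_2 = 1$ h⁻¹), and all three cycle-1 scans in the window.  Recovering the
input from the four sparse plasma samples instead transfers the terminal
slope's sampling error into the abscissa and adds several points of
median error; that variant is exposed through `fitInputFunction()` but is
not the protocol's default.

# Known limitations

The generator's defaults are calibrated to published *summary* statistics,
not to patient-level data (none are deposited), so distributional shapes
beyond the matched medians, IQRs, means and SDs are modelling choices.
The cycle-1 ratio medians are reproduced with ~5% structural error, as
discussed above.  Organ parameters other than spleen and lungs are
synthetic.  The occupancy model is a dose-level Hill function; mechanistic
occupancy dynamics, reference-tissue methods and nonlinear compartmental
fitting are out of scope, as are image reconstruction, segmentation and
the RNA-seq processing chain of the original study.
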