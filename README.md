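# ImmunoPatlak

Kinetic quantification and cohort simulation for zirconium-89 immuno-PET
antibody studies with mass-dose escalation.

## What this package is for

⁸⁹Zr-labelled monoclonal antibodies can be imaged by PET over several
days, and for immune-checkpoint targets such as LAG-3 the key questions
are whether the tumor signal is quantifiable and whether it is
target-specific. The design this package analyses answers both by dose
escalation: each patient is imaged after a tracer-only antibody dose
(4 mg) and again after an unlabeled pre-dose raising the total mass dose
to 44 mg or 604 mg. Target-mediated uptake is progressively blocked;
non-specific uptake is not.

The package is aimed at molecular-imaging and pharmacometrics analysts.
It provides, as tested reusable components:

- **Quantification** — decay correction (⁸⁹Zr half-life 78.41 h), percent
  injected activity per litre (%IA/L), SUV, and organ-/tumor-to-plasma
  ratios with nearest-time blood pairing. Ratios are the primary outcome:
  antibody clearance is dose-dependent, which confounds SUV.
- **Patlak graphical analysis** — bi-exponential (or log-linear) plasma
  input-function fitting with exact integrals, transformation to Patlak
  coordinates, and OLS estimation of the net irreversible uptake rate.
  For an irreversibly trapped tracer with plasma input \(C_p\) and tissue
  concentration \(C_t\), late points of
  \(y = C_t(t)/C_p(t)\) against \(x = \int_0^t C_p\,d\tau / C_p(t)\)
  fall on a line with slope \(K_i/1000\)
  (\(K_i = 1000\,k_1 k_3/(k_2+k_3)\), μL g⁻¹ h⁻¹) and intercept the
  reversible distribution volume.
- **Saturation metrics and dose statistics** — blocked-fraction reports
  (`Ki_eff = Ki_ns + Ki_spec·(1−occ)`, occupancy a Hill function of mass
  dose), ANOVA + Tukey HSD for plasma, Kruskal–Wallis + exact pairwise
  Wilcoxon rank-sum with Bonferroni correction for lesions.
- **Immune linkage** — a mean z-score gene-signature surrogate, Spearman
  correlation with exact permutation p-values at small n, and
  immune-desert vs infiltrated phenotype classification.
- **A synthetic-cohort generator** — seeded, fully deterministic cohorts
  (6 patients, two imaging cycles, 2–5 lesions each, saturable
  irreversible uptake, immune-infiltration latent variable, measurement
  noise) calibrated against the published summary statistics of the
  emulated anti-LAG-3 study, with ground truth retained for
  parameter-recovery work. No patient-level data exist publicly; the
  simulator stands in for them.

See the methods vignette (`vignettes/immuno-pet-kinetics.Rmd`) for the
models, calibrations, design decisions and limitations.

## Worked example

Noise-free spleen recovery — the Patlak estimate reproduces the uptake
rate the curve was generated with:

```r
library(ImmunoPatlak)
occ <- calibrateOccupancy()$model        # Hill d50 ~ 11.9 mg, h = 2
sp  <- spleenParams()
inp <- plasmaModelForDose(4)
tac <- simulateTissueCurve(sp, receptorOccupancy(4, occ), inp, c(2, 90, 138))
patlakFit(patlakTransform(tac, inp))
#> PatlakFit: Ki = 30.06 uL/g/h, V = 0.4977 mL/g, R^2 = 1.0000 (n = 2)
```

A full synthetic cohort, end to end:

```r
coh <- generateCohort(CohortConfig(seed = 42))
coh
#> PETCohort: 6 patients, 16 lesions, 260 TAC rows, seed 42

up  <- uptakeTable(coh)                  # decay-correct, %IA/L, SUV, ratios
cmp <- compareDoseGroups(up, time_h = 138)
vapply(cmp$groups, median, 0)            # lesion ratio medians by dose
#>         4        44       604
#> 2.5008559 0.6781669 0.5342554
cmp$pairwise
#>        pair statistic        p_raw   p_adjusted
#> 1   4 vs 44       123 5.166757e-05 1.550027e-04
#> 2  4 vs 604       128 2.719346e-06 8.158038e-06
#> 3 44 vs 604        45 1.948718e-01 5.846154e-01
```

Tumor uptake is high at the tracer-only dose, collapses at both blocking
doses, and the two blocking doses are statistically indistinguishable —
the saturation signature. Spleen Patlak rates tell the same story:

```r
pat <- patlakTable(coh)
ki  <- vapply(split(pat, ~ mass_dose_mg)[c("4", "44", "604")],
              function(d) mean(d$ki_ul_g_h[d$region_id == "spleen"]), 0)
saturationReport(ki, "4", "604")
#>   dose        ki fraction_blocked classification
#> 1    4 32.277958        0.0000000           none
#> 2   44  3.845757        0.9237743        partial
#> 3  604  1.499659        1.0000000           full
```

`immuneSummary(coh)` adds per-patient phenotype labels (mean 138-h ratio
≥ 3 → infiltrated), signature scores and simulated LAG-3
immunohistochemistry; `runPipeline(list(seed = 42), out_dir = "out")`
executes all stages and writes the CSV/JSON outputs plus a readable
report, and `inst/cli/immunopatlak.R` wraps the same stages for shell use.

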