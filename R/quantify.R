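## Unit and ratio arithmetic: decay correction, %IA/L, SUV,
## tissue-to-plasma ratios, and the cohort-level uptake table.

#' Decay correction
#'
#' Corrects a measured activity concentration back to the reference
#' (injection) time: `conc * 2^(elapsed / half_life)`.  The default
#' half-life is the physical half-life of zirconium-89 (78.41 h).
#' `decayUncorrect` is the exact inverse.
#'
#' @param conc measured concentration (any activity unit); vectorized.
#' @param elapsed hours between reference time and measurement (>= 0).
#' @param half_life isotope half-life, h (> 0).
#' @return corrected concentration, same unit.
#' @examples
#' decayCorrect(100, 78.41)            # one half-life doubles
#' decayUncorrect(decayCorrect(50, 90), 90)  # identity
#' @export
decayCorrect <- function(conc, elapsed, half_life = zr89HalfLife()) {
  if (any(elapsed < 0)) stop("elapsed must be >= 0")
  if (!isTRUE(all(half_life > 0))) stop("half_life must be > 0")
  conc * 2^(elapsed / half_life)
}

#' @rdname decayCorrect
#' @export
decayUncorrect <- function(conc, elapsed, half_life = zr89HalfLife()) {
  if (any(elapsed < 0)) stop("elapsed must be >= 0")
  if (!isTRUE(all(half_life > 0))) stop("half_life must be > 0")
  conc * 2^(-elapsed / half_life)
}

#' Percent injected activity per litre
#'
#' Converts a decay-corrected concentration in Bq/mL to \%IA/L:
#' `100 * conc * 1000 / injected_activity[Bq]`.  A body-size-independent
#' concentration unit.
#'
#' @param conc_dc decay-corrected concentration, Bq/mL; vectorized.
#' @param inj an [InjectionRecord-class].
#' @return \%IA/L.
#' @examples
#' percentInjectedActivity(37, InjectionRecord(activity_mbq = 37))  # 0.1
#' @export
percentInjectedActivity <- function(conc_dc, inj) {
  stopifnot(is(inj, "InjectionRecord"))
  validObject(inj)
  100 * conc_dc * 1000 / (inj@activity_mbq * 1e6)
}

#' Standardized uptake value
#'
#' `SUV = conc_dc / (injected_activity[Bq] / body_weight[g])`, with the
#' 1 g/mL tissue-density convention.  SUV assumes comparable clearance
#' between groups, which does not hold across antibody mass doses; the
#' package computes it for completeness, but tissue-to-plasma ratios are
#' the preferred uptake measure.
#'
#' @inheritParams percentInjectedActivity
#' @return dimensionless SUV.
#' @examples
#' suv(500, InjectionRecord(37, 4, 74))  # 1.0
#' @export
suv <- function(conc_dc, inj) {
  stopifnot(is(inj, "InjectionRecord"))
  validObject(inj)
  conc_dc / (inj@activity_mbq * 1e6 / (inj@weight_kg * 1000))
}

#' Tissue-to-plasma ratio with nearest-time pairing
#'
#' Divides each tissue sample by the plasma concentration measured closest
#' in time, requiring the pair to lie within `tolerance_h` (blood was drawn
#' after every scan, so scan/draw offsets are small).  Both inputs must be
#' decay-corrected and in the same units; the ratio is invariant under any
#' common rescaling.
#'
#' @param tissue a [TimeActivityCurve-class] (decay-corrected).
#' @param plasma a [TimeActivityCurve-class] of plasma samples in the same
#'   units.
#' @param tolerance_h maximal pairing offset, h (default 6).
#' @return data.frame with `time_h`, `plasma_time_h`, `ratio`.
#' @examples
#' tis <- TimeActivityCurve("spleen", c(90, 138), c(12, 10))
#' pl <- TimeActivityCurve("plasma", c(1, 91, 139), c(20, 6, 3),
#'                         region_type = "plasma")
#' tissueToPlasmaRatio(tis, pl)
#' @export
tissueToPlasmaRatio <- function(tissue, plasma, tolerance_h = 6) {
  stopifnot(is(tissue, "TimeActivityCurve"), is(plasma, "TimeActivityCurve"))
  if (tissue@units != plasma@units)
    stop("tissue and plasma must be in the same units")
  tt <- tacTimes(tissue); pt <- tacTimes(plasma)
  idx <- vapply(tt, function(t) which.min(abs(pt - t)), 1L)
  off <- abs(pt[idx] - tt)
  if (any(off > tolerance_h))
    stop(sprintf("no plasma sample within %g h of tissue time(s) %s",
                 tolerance_h, paste(tt[off > tolerance_h], collapse = ", ")))
  pc <- tacConc(plasma)[idx]
  if (any(pc <= 0)) stop("plasma concentration must be positive for ratios")
  data.frame(time_h = tt, plasma_time_h = pt[idx],
             ratio = tacConc(tissue) / pc)
}

#' Uptake measures for every region of a cohort
#'
#' Runs the quantification pipeline over a simulated (or read-in) cohort:
#' measured region activities (Bq/mL) are decay-corrected to the injection
#' time of their cycle, converted to \%IA/L and SUV, and divided by the
#' nearest plasma sample to give tissue-to-plasma ratios.  Plasma samples
#' themselves are reported as \%IA/L.
#'
#' @param cohort a [PETCohort-class].
#' @param tolerance_h plasma pairing tolerance, h.
#' @param half_life isotope half-life, h.
#' @return data.frame with columns patient_id, region_id, region_type,
#'   cycle, mass_dose_mg, time_h, measure_kind
#'   (`tissue_to_plasma` | `suv_peak` | `pct_ia_per_l`), value.
#' @examples
#' up <- uptakeTable(generateCohort(CohortConfig(seed = 1)))
#' head(up)
#' @export
uptakeTable <- function(cohort, tolerance_h = 6, half_life = zr89HalfLife()) {
  stopifnot(is(cohort, "PETCohort"))
  inj <- cohort@injections
  out <- list()
  add <- function(pid, rid, rtype, cyc, dose, time, kind, value) {
    out[[length(out) + 1L]] <<- data.frame(
      patient_id = pid, region_id = rid, region_type = rtype, cycle = cyc,
      mass_dose_mg = dose, time_h = time, measure_kind = kind, value = value)
  }
  for (i in seq_len(nrow(inj))) {
    pid <- inj$patient_id[i]; cyc <- inj$cycle[i]
    rec <- InjectionRecord(inj$activity_mbq[i], inj$mass_mg[i],
                           inj$weight_kg[i], inj$t0_iso8601[i], cyc)
    pl <- cohort@plasma[cohort@plasma$patient_id == pid &
                          cohort@plasma$cycle == cyc, ]
    if (nrow(pl) == 0) next
    add(pid, "plasma", "plasma", cyc, inj$mass_mg[i], pl$time_h,
        "pct_ia_per_l", pl$conc_pct_ia_per_l)
    ptac <- TimeActivityCurve("plasma", pl$time_h, pl$conc_pct_ia_per_l,
                              region_type = "plasma", cycle = cyc)
    tt <- cohort@tac[cohort@tac$patient_id == pid & cohort@tac$cycle == cyc, ]
    for (rid in unique(tt$region_id)) {
      rr <- tt[tt$region_id == rid, ]
      dc <- decayCorrect(rr$conc_bq_per_ml, rr$time_h, half_life)
      ial <- percentInjectedActivity(dc, rec)
      tac <- TimeActivityCurve(rid, rr$time_h, ial,
                               region_type = rr$region_type[1], cycle = cyc)
      rat <- tryCatch(tissueToPlasmaRatio(tac, ptac, tolerance_h),
                      error = function(e) NULL)
      if (!is.null(rat))
        add(pid, rid, rr$region_type[1], cyc, inj$mass_mg[i], rat$time_h,
            "tissue_to_plasma", rat$ratio)
      add(pid, rid, rr$region_type[1], cyc, inj$mass_mg[i], rr$time_h,
          "suv_peak", suv(dc, rec))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
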