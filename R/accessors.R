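#' Construct a TimeActivityCurve
#'
#' @param region_id region identifier.
#' @param times hours post injection, strictly increasing.
#' @param conc concentrations, same length as `times`.
#' @param region_type `"organ"`, `"tumor"`, `"plasma"` or `"blood"`.
#' @param cycle imaging cycle (1 or 2).
#' @param units `"Bq/mL"`, `"%IA/L"`, `"SUV"` or `"ratio"`.
#' @param decay_corrected logical decay-correction state.
#' @return A [TimeActivityCurve-class] object.
#' @examples
#' TimeActivityCurve("spleen", times = c(2, 90, 138), conc = c(5, 4, 3))
#' @export
TimeActivityCurve <- function(region_id, times, conc, region_type = "organ",
                              cycle = 1L, units = "%IA/L",
                              decay_corrected = TRUE) {
  new("TimeActivityCurve", region_id = as.character(region_id),
      region_type = region_type, cycle = as.integer(cycle),
      times = as.numeric(times), conc = as.numeric(conc), units = units,
      decay_corrected = decay_corrected)
}

#' Construct an InjectionRecord
#'
#' @param activity_mbq injected activity, MBq.
#' @param mass_mg total antibody mass dose, mg.
#' @param weight_kg body weight, kg.
#' @param t0 ISO-8601 injection timestamp.
#' @param cycle imaging cycle.
#' @return An [InjectionRecord-class] object.
#' @examples
#' InjectionRecord(37, 4, 75)
#' @export
InjectionRecord <- function(activity_mbq = 37, mass_mg = 4, weight_kg = 75,
                            t0 = "2020-01-01T10:00:00Z", cycle = 1L) {
  new("InjectionRecord", activity_mbq = activity_mbq, mass_mg = mass_mg,
      weight_kg = weight_kg, t0 = t0, cycle = as.integer(cycle))
}

#' Construct PlasmaPKParams
#'
#' @param amp_fast,amp_slow amplitudes, \%IA/L.
#' @param lambda_fast,lambda_slow rate constants, 1/h.
#' @param clearance_scale dimensionless multiplier on `lambda_slow`.
#' @return A [PlasmaPKParams-class] object.
#' @examples
#' PlasmaPKParams(25, 8, 0.5, 0.014)
#' @export
PlasmaPKParams <- function(amp_fast, amp_slow, lambda_fast, lambda_slow,
                           clearance_scale = 1) {
  new("PlasmaPKParams", amp_fast = amp_fast, amp_slow = amp_slow,
      lambda_fast = lambda_fast, lambda_slow = lambda_slow,
      clearance_scale = clearance_scale)
}

#' Construct an OccupancyModel
#'
#' @param d50 mass dose at half-maximal occupancy, mg.
#' @param hill Hill exponent.
#' @return An [OccupancyModel-class] object.
#' @examples
#' receptorOccupancy(12, OccupancyModel(d50 = 12, hill = 2))
#' @export
OccupancyModel <- function(d50, hill = 2) {
  new("OccupancyModel", d50 = d50, hill = hill)
}

#' Construct TissueKineticParams
#'
#' @param vb fractional blood/distribution volume.
#' @param k1 plasma-to-tissue transfer, mL g^-1 h^-1.
#' @param k2 efflux, 1/h.
#' @param k3_max maximal irreversible trapping rate, 1/h.
#' @param ki_nonspec non-saturable irreversible floor, uL g^-1 h^-1.
#' @return A [TissueKineticParams-class] object.
#' @examples
#' TissueKineticParams(vb = 0.25, k1 = 0.098, k2 = 0.2, k3_max = 0.1,
#'                     ki_nonspec = 0.67)
#' @export
TissueKineticParams <- function(vb = 0.1, k1 = 0.05, k2 = 0.2, k3_max = 0,
                                ki_nonspec = 0) {
  new("TissueKineticParams", vb = vb, k1 = k1, k2 = k2, k3_max = k3_max,
      ki_nonspec = ki_nonspec)
}

## ---- generics ----

#' Accessors for time-activity curves and fit objects
#'
#' `tacTimes` and `tacConc` return the sampling times (h) and concentrations
#' of a [TimeActivityCurve-class]; `regionId` and `regionType` its identity;
#' `kiValue`, `vIntercept` and `rSquared` extract the slope-derived net
#' uptake rate (uL g^-1 h^-1), intercept and fit quality of a
#' [PatlakFit-class].
#'
#' @param object a `TimeActivityCurve` or `PatlakFit`.
#' @return numeric (or character) scalar/vector as appropriate.
#' @name accessors
#' @examples
#' tac <- TimeActivityCurve("spleen", c(2, 90, 138), c(5, 4, 3))
#' tacTimes(tac)
NULL

#' @rdname accessors
#' @export
setGeneric("tacTimes", function(object) standardGeneric("tacTimes"))
#' @rdname accessors
#' @export
setGeneric("tacConc", function(object) standardGeneric("tacConc"))
#' @rdname accessors
#' @export
setGeneric("regionId", function(object) standardGeneric("regionId"))
#' @rdname accessors
#' @export
setGeneric("regionType", function(object) standardGeneric("regionType"))
#' @rdname accessors
#' @export
setGeneric("kiValue", function(object) standardGeneric("kiValue"))
#' @rdname accessors
#' @export
setGeneric("vIntercept", function(object) standardGeneric("vIntercept"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @rdname accessors
setMethod("tacTimes", "TimeActivityCurve", function(object) object@times)
#' @rdname accessors
setMethod("tacConc", "TimeActivityCurve", function(object) object@conc)
#' @rdname accessors
setMethod("regionId", "TimeActivityCurve", function(object) object@region_id)
#' @rdname accessors
setMethod("regionType", "TimeActivityCurve", function(object) object@region_type)
#' @rdname accessors
setMethod("kiValue", "PatlakFit", function(object) object@ki)
#' @rdname accessors
setMethod("vIntercept", "PatlakFit", function(object) object@v_intercept)
#' @rdname accessors
setMethod("rSquared", "PatlakFit", function(object) object@r_squared)

#' Cohort accessors
#'
#' Extract the observed tables, configuration or retained ground truth from
#' a simulated [PETCohort-class].
#'
#' @param object a `PETCohort`.
#' @return `cohortConfig` returns the [CohortConfig-class]; the table
#'   accessors return data.frames; `cohortTruth` returns the list of
#'   ground-truth tables.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("cohortConfig", function(object) standardGeneric("cohortConfig"))
#' @rdname cohort-accessors
#' @export
setGeneric("plasmaSamples", function(object) standardGeneric("plasmaSamples"))
#' @rdname cohort-accessors
#' @export
setGeneric("tissueSamples", function(object) standardGeneric("tissueSamples"))
#' @rdname cohort-accessors
#' @export
setGeneric("injectionRecords", function(object) standardGeneric("injectionRecords"))
#' @rdname cohort-accessors
#' @export
setGeneric("lesionTruth", function(object) standardGeneric("lesionTruth"))
#' @rdname cohort-accessors
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))

#' @rdname cohort-accessors
setMethod("cohortConfig", "PETCohort", function(object) object@config)
#' @rdname cohort-accessors
setMethod("plasmaSamples", "PETCohort", function(object) object@plasma)
#' @rdname cohort-accessors
setMethod("tissueSamples", "PETCohort", function(object) object@tac)
#' @rdname cohort-accessors
setMethod("injectionRecords", "PETCohort", function(object) object@injections)
#' @rdname cohort-accessors
setMethod("lesionTruth", "PETCohort", function(object) object@lesions)
#' @rdname cohort-accessors
setMethod("cohortTruth", "PETCohort", function(object) object@truth)

## ---- show methods ----

setMethod("show", "TimeActivityCurve", function(object) {
  cat(sprintf("TimeActivityCurve '%s' (%s, cycle %d): %d samples, %s%s\n",
              object@region_id, object@region_type, object@cycle,
              length(object@times), object@units,
              if (object@decay_corrected) ", decay-corrected" else ""))
  if (length(object@times)) {
    cat("  t (h): ", paste(signif(object@times, 4), collapse = ", "), "\n")
    cat("  conc : ", paste(signif(object@conc, 4), collapse = ", "), "\n")
  }
})

setMethod("show", "PatlakFit", function(object) {
  cat(sprintf("PatlakFit: Ki = %.4g uL/g/h, V = %.4g mL/g, R^2 = %.4f (n = %d)\n",
              object@ki, object@v_intercept, object@r_squared, object@n_points))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "InputFunctionFit", function(object) {
  cat(sprintf("InputFunctionFit (%s), relative RMS residual %.3g\n",
              object@model, object@fit_residual))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d patients, cycle-2 arms {%s}, seed %d\n",
              object@n_patients,
              paste(sort(unique(object@arm_assignment)), collapse = ", "),
              object@seed))
})

setMethod("show", "PETCohort", function(object) {
  cat(sprintf("PETCohort: %d patients, %d lesions, %d TAC rows, seed %d\n",
              object@config@n_patients, nrow(object@lesions),
              nrow(object@tac), object@provenance$seed))
})
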