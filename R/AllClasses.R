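#' @import methods
NULL

#' Sampled activity concentration of one region over time
#'
#' A `TimeActivityCurve` holds the sampled concentration of a single region
#' (an organ, a tumor lesion, plasma or whole blood) over time, together with
#' its unit and decay-correction state.  Times are hours post injection and
#' must be strictly increasing; concentrations are non-negative.
#'
#' @slot region_id single character identifier of the region.
#' @slot region_type one of `"organ"`, `"tumor"`, `"plasma"`, `"blood"`.
#' @slot cycle imaging cycle the curve belongs to (1 or 2).
#' @slot times numeric vector, hours post injection, strictly increasing.
#' @slot conc numeric vector of concentrations, same length as `times`.
#' @slot units one of `"Bq/mL"`, `"%IA/L"`, `"SUV"`, `"ratio"`.
#' @slot decay_corrected logical flag; `TRUE` when `conc` has been corrected
#'   to the injection time of the relevant cycle.
#'
#' @seealso [TimeActivityCurve()] for the constructor.
#' @export
setClass("TimeActivityCurve",
  representation(
    region_id = "character",
    region_type = "character",
    cycle = "integer",
    times = "numeric",
    conc = "numeric",
    units = "character",
    decay_corrected = "logical"
  ),
  prototype(region_id = "region", region_type = "organ", cycle = 1L,
            units = "%IA/L", decay_corrected = TRUE)
)

setValidity("TimeActivityCurve", function(object) {
  msg <- character()
  if (length(object@region_id) != 1L) msg <- c(msg, "region_id must be length 1")
  if (!object@region_type %in% c("organ", "tumor", "plasma", "blood"))
    msg <- c(msg, "region_type must be organ|tumor|plasma|blood")
  if (!object@cycle %in% c(1L, 2L)) msg <- c(msg, "cycle must be 1 or 2")
  if (length(object@times) != length(object@conc))
    msg <- c(msg, "times and conc must have equal length")
  if (length(object@times) && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@conc) && (any(!is.finite(object@conc)) || any(object@conc < 0)))
    msg <- c(msg, "conc must be finite and non-negative")
  if (!object@units %in% c("Bq/mL", "%IA/L", "SUV", "ratio"))
    msg <- c(msg, "units must be one of Bq/mL, %IA/L, SUV, ratio")
  if (length(msg)) msg else TRUE
})

#' Injection record
#'
#' Administered activity, total antibody mass dose (tracer plus any unlabeled
#' pre-dose), body weight and injection time for one tracer administration.
#' This is the denominator information for percent-injected-activity and SUV.
#'
#' @slot activity_mbq injected activity in MBq (> 0).
#' @slot mass_mg total antibody mass dose in mg (>= tracer mass).
#' @slot weight_kg body weight in kg (> 0).
#' @slot t0 ISO-8601 timestamp of the injection.
#' @slot cycle imaging cycle (1 or 2).
#' @export
setClass("InjectionRecord",
  representation(activity_mbq = "numeric", mass_mg = "numeric",
                 weight_kg = "numeric", t0 = "character", cycle = "integer"),
  prototype(activity_mbq = 37, mass_mg = 4, weight_kg = 75,
            t0 = "2020-01-01T10:00:00Z", cycle = 1L)
)

setValidity("InjectionRecord", function(object) {
  msg <- character()
  if (!isTRUE(object@activity_mbq > 0)) msg <- c(msg, "activity_mbq must be > 0")
  if (!isTRUE(object@mass_mg > 0)) msg <- c(msg, "mass_mg must be > 0")
  if (!isTRUE(object@weight_kg > 0)) msg <- c(msg, "weight_kg must be > 0")
  if (!object@cycle %in% c(1L, 2L)) msg <- c(msg, "cycle must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Bi-exponential plasma disposition parameters
#'
#' Decay-corrected plasma concentration of the tracer, in percent injected
#' activity per litre, is modelled as
#' \deqn{C_p(t) = A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 s t}}
#' with a fast distribution phase (\eqn{A_1,\lambda_1}), a slow terminal
#' phase (\eqn{A_2,\lambda_2}) and a dimensionless clearance scale \eqn{s}
#' that carries the mass-dose dependence of the terminal clearance
#' (target-mediated disposition: low mass doses clear faster).
#'
#' @slot amp_fast fast-phase amplitude, \%IA/L (>= 0).
#' @slot amp_slow slow-phase amplitude, \%IA/L (>= 0).
#' @slot lambda_fast fast rate constant, 1/h.
#' @slot lambda_slow slow rate constant, 1/h; `lambda_fast > lambda_slow > 0`.
#' @slot clearance_scale dimensionless multiplier on `lambda_slow`.
#' @export
setClass("PlasmaPKParams",
  representation(amp_fast = "numeric", amp_slow = "numeric",
                 lambda_fast = "numeric", lambda_slow = "numeric",
                 clearance_scale = "numeric"),
  prototype(clearance_scale = 1)
)

setValidity("PlasmaPKParams", function(object) {
  msg <- character()
  if (object@amp_fast < 0 || object@amp_slow < 0)
    msg <- c(msg, "amplitudes must be >= 0")
  if (object@amp_fast + object@amp_slow <= 0)
    msg <- c(msg, "Cp(0) = amp_fast + amp_slow must be > 0")
  if (!(object@lambda_fast > object@lambda_slow && object@lambda_slow > 0))
    msg <- c(msg, "need lambda_fast > lambda_slow > 0")
  if (!isTRUE(object@clearance_scale > 0))
    msg <- c(msg, "clearance_scale must be > 0")
  if (length(msg)) msg else TRUE
})

#' Receptor-occupancy model
#'
#' Fractional occupancy of the target by unlabeled antibody as a Hill
#' function of the administered mass dose:
#' \deqn{occ(D) = D^h / (D^h + D_{50}^h).}
#' Occupancy is 0 at dose 0, strictly increasing, and always < 1.
#'
#' @slot d50 mass dose (mg) at half-maximal occupancy (> 0).
#' @slot hill dimensionless Hill exponent (> 0).
#' @export
setClass("OccupancyModel",
  representation(d50 = "numeric", hill = "numeric"),
  prototype(d50 = 12, hill = 2)
)

setValidity("OccupancyModel", function(object) {
  msg <- character()
  if (!isTRUE(object@d50 > 0)) msg <- c(msg, "d50 must be > 0")
  if (!isTRUE(object@hill > 0)) msg <- c(msg, "hill must be > 0")
  if (length(msg)) msg else TRUE
})

#' Irreversible two-tissue kinetic parameters
#'
#' Parameters of the irreversible two-tissue compartment model used for all
#' simulated regions.  The target-specific net influx rate implied by the
#' rate constants is
#' \deqn{K_i^{spec} = 1000\, k_1 k_3^{max} / (k_2 + k_3^{max})}
#' in \eqn{\mu}L g\eqn{^{-1}} h\eqn{^{-1}}; the non-specific floor
#' `ki_nonspec` is an additional irreversible component that cannot be
#' blocked by unlabeled antibody.
#'
#' @slot vb dimensionless fractional blood/distribution volume.
#' @slot k1 plasma-to-tissue transfer, mL g^-1 h^-1.
#' @slot k2 tissue-to-plasma efflux, 1/h.
#' @slot k3_max maximal irreversible trapping rate, 1/h (internalization).
#' @slot ki_nonspec non-saturable irreversible floor, uL g^-1 h^-1.
#' @export
setClass("TissueKineticParams",
  representation(vb = "numeric", k1 = "numeric", k2 = "numeric",
                 k3_max = "numeric", ki_nonspec = "numeric"),
  prototype(vb = 0.1, k1 = 0.05, k2 = 0.2, k3_max = 0, ki_nonspec = 0)
)

setValidity("TissueKineticParams", function(object) {
  msg <- character()
  vals <- c(object@vb, object@k1, object@k2, object@k3_max, object@ki_nonspec)
  if (any(!is.finite(vals)) || any(vals < 0))
    msg <- c(msg, "all parameters must be finite and >= 0")
  if (object@k1 > 0 && object@k2 + object@k3_max > 0) {
    kspec <- 1000 * object@k1 * object@k3_max / (object@k2 + object@k3_max)
    if (kspec > 1000 * object@k1 + 1e-9)
      msg <- c(msg, "implied specific Ki exceeds 1000*k1")
  }
  if (length(msg)) msg else TRUE
})

#' Continuous plasma input-function model
#'
#' A fitted continuous model of the plasma concentration, used as the input
#' function of the Patlak analysis.  Two dialects are supported: a
#' bi-exponential model with closed-form time integral, and a piecewise
#' log-linear interpolant of the samples whose integral is computed by the
#' exact piecewise-exponential formula.
#'
#' @slot model `"biexponential"` or `"loglinear_interp"`.
#' @slot params named list: `A1, l1, A2, l2` for the bi-exponential model;
#'   `knot_t`, `knot_c` for the interpolant.
#' @slot fit_residual relative root-mean-square residual of the fit.
#' @export
setClass("InputFunctionFit",
  representation(model = "character", params = "list", fit_residual = "numeric"),
  prototype(model = "biexponential", fit_residual = 0)
)

setValidity("InputFunctionFit", function(object) {
  msg <- character()
  if (!object@model %in% c("biexponential", "loglinear_interp"))
    msg <- c(msg, "model must be biexponential or loglinear_interp")
  if (object@model == "biexponential" &&
      !all(c("A1", "l1", "A2", "l2") %in% names(object@params)))
    msg <- c(msg, "biexponential params need A1, l1, A2, l2")
  if (object@model == "loglinear_interp" &&
      !all(c("knot_t", "knot_c") %in% names(object@params)))
    msg <- c(msg, "loglinear_interp params need knot_t, knot_c")
  if (length(msg)) msg else TRUE
})

#' Patlak fit result
#'
#' Slope and intercept of the ordinary-least-squares line through the
#' Patlak-transformed points.  The slope times 1000 is the net irreversible
#' uptake rate Ki in \eqn{\mu}L g\eqn{^{-1}} h\eqn{^{-1}} (tissue density
#' 1 g/mL); the intercept reflects the reversible distribution volume.
#' Negative fitted slopes are reported with a flag, never clamped.
#'
#' @slot ki net irreversible uptake rate, uL g^-1 h^-1 (slope x 1000).
#' @slot v_intercept intercept, mL/g.
#' @slot r_squared coefficient of determination (1 when only two points).
#' @slot n_points number of points used.
#' @slot window numeric length-2, the time window (h) used.
#' @slot flags character vector of quality flags (e.g. "negative_slope").
#' @export
setClass("PatlakFit",
  representation(ki = "numeric", v_intercept = "numeric", r_squared = "numeric",
                 n_points = "integer", window = "numeric", flags = "character"),
  prototype(flags = character())
)

setValidity("PatlakFit", function(object) {
  if (object@n_points < 2L) "n_points must be >= 2" else TRUE
})

#' Cohort simulation configuration
#'
#' Study-design parameters of the synthetic cohort generator.  Defaults
#' reproduce the design of the emulated trial: 6 patients, each imaged in
#' cycle 1 at a 4-mg antibody mass dose (scans < 2, 90 and 138 h post
#' injection) and in cycle 2 after an unlabeled pre-dose reaching 44 mg
#' (3 patients) or 604 mg (3 patients), with venous blood sampled 1 h post
#' injection and after every scan, and 2--5 tumor lesions per patient.
#'
#' @slot n_patients number of patients (default 6).
#' @slot patient_ids character identifiers, length `n_patients`.
#' @slot arm_assignment named numeric, cycle-2 total mass dose (44 or 604 mg)
#'   per patient id.
#' @slot scan_times_c1 cycle-1 scan times, h post injection.
#' @slot scan_times_c2 cycle-2 scan times, h post injection.
#' @slot blood_times_c1 cycle-1 blood-sampling times, h post injection.
#' @slot blood_times_c2 cycle-2 blood-sampling times, h post injection.
#' @slot lesions_min,lesions_max per-patient lesion count range (capped at 5).
#' @slot noise_cv fractional SD of the multiplicative measurement noise.
#' @slot seed integer seed; the cohort is a pure function of config + seed.
#' @slot injected_activity injected activity, MBq (default 37).
#' @slot tracer_mass antibody mass of the tracer itself, mg (default 4).
#' @slot scan_jitter add uniform +-1 h jitter to the late scan times.
#' @slot drop_blood_sample drop one 90-h blood sample (missing-data exercise).
#' @export
setClass("CohortConfig",
  representation(
    n_patients = "integer", patient_ids = "character",
    arm_assignment = "numeric",
    scan_times_c1 = "numeric", scan_times_c2 = "numeric",
    blood_times_c1 = "numeric", blood_times_c2 = "numeric",
    lesions_min = "integer", lesions_max = "integer",
    noise_cv = "numeric", seed = "integer",
    injected_activity = "numeric", tracer_mass = "numeric",
    scan_jitter = "logical", drop_blood_sample = "logical"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@n_patients < 1L) msg <- c(msg, "n_patients must be >= 1")
  if (length(object@patient_ids) != object@n_patients)
    msg <- c(msg, "patient_ids must have length n_patients")
  if (anyDuplicated(object@patient_ids))
    msg <- c(msg, "patient_ids must be unique")
  if (!setequal(names(object@arm_assignment), object@patient_ids))
    msg <- c(msg, "arm_assignment must be named by patient_ids")
  if (!all(object@arm_assignment %in% c(44, 604)))
    msg <- c(msg, "cycle-2 arm doses must be 44 or 604 mg")
  for (nm in c("scan_times_c1", "scan_times_c2", "blood_times_c1", "blood_times_c2")) {
    tt <- slot(object, nm)
    if (!length(tt) || any(tt <= 0) || any(diff(tt) <= 0))
      msg <- c(msg, paste(nm, "must be positive and strictly increasing"))
  }
  if (object@lesions_min < 1L || object@lesions_max > 5L ||
      object@lesions_min > object@lesions_max)
    msg <- c(msg, "lesion count range must satisfy 1 <= min <= max <= 5")
  if (object@noise_cv < 0) msg <- c(msg, "noise_cv must be >= 0")
  if (!isTRUE(object@injected_activity > 0))
    msg <- c(msg, "injected_activity must be > 0")
  if (!isTRUE(object@tracer_mass > 0)) msg <- c(msg, "tracer_mass must be > 0")
  if (length(msg)) msg else TRUE
})

#' Simulated imaging cohort with retained ground truth
#'
#' Container for one simulated cohort: the "observed" (noisy) plasma samples
#' and region time-activity data, the injection records, and -- stored
#' separately -- the generating ground truth (patient plasma parameters,
#' per-region kinetic parameters, lesion infiltration) needed for
#' parameter-recovery studies.
#'
#' Observed tables:
#' \describe{
#'   \item{plasma}{patient_id, cycle, time_h, conc_pct_ia_per_l
#'     (decay-corrected well-counter values).}
#'   \item{tac}{patient_id, region_id, region_type, cycle, time_h,
#'     conc_bq_per_ml (image values, \emph{not} decay-corrected).}
#'   \item{injections}{patient_id, cycle, activity_mbq, mass_mg, weight_kg,
#'     t0_iso8601.}
#'   \item{lesions}{lesion metadata incl. simulated immunohistochemistry
#'     percentage (observed columns) next to ground-truth columns.}
#' }
#'
#' @slot config the [CohortConfig-class] used.
#' @slot injections data.frame of injection records.
#' @slot plasma data.frame of plasma samples.
#' @slot tac data.frame of region time-activity samples.
#' @slot lesions data.frame of lesion metadata and truth.
#' @slot truth list of ground-truth tables (`plasma_params`, `organ_params`,
#'   `lesion_params`, `occupancy`, `patients`).
#' @slot provenance list with `seed` and `config_hash`.
#' @export
setClass("PETCohort",
  representation(config = "CohortConfig", injections = "data.frame",
                 plasma = "data.frame", tac = "data.frame",
                 lesions = "data.frame", truth = "list", provenance = "list")
)
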