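## Synthetic cohort generation: dose-dependent plasma PK, saturable
## irreversible tissue uptake, immune-infiltration latent variable.

#' Build a cohort configuration
#'
#' Constructor with the emulated study design as defaults: six patients
#' imaged at a 4-mg mass dose in cycle 1 (scans at 2, 90, 138 h) and after
#' an unlabeled pre-dose reaching 44 mg (patients 6, 9, 10) or 604 mg
#' (patients 1, 2, 3) in cycle 2 (scans at 90, 138 h); venous blood at 1 h
#' and after every scan; 2--5 lesions per patient; 37 MBq and 4 mg of
#' tracer; 10\% multiplicative measurement noise.
#'
#' @param n_patients number of patients.
#' @param patient_ids character ids (defaults to the study numbering).
#' @param arm_assignment named numeric of cycle-2 doses (44/604) per patient.
#' @param scan_times_c1,scan_times_c2 scan times, h post injection.
#' @param blood_times_c1,blood_times_c2 blood-draw times, h post injection.
#' @param lesions_min,lesions_max per-patient lesion count range (max 5).
#' @param noise_cv fractional SD of multiplicative measurement noise.
#' @param seed integer seed.
#' @param injected_activity MBq per injection.
#' @param tracer_mass antibody mass of the tracer, mg.
#' @param scan_jitter add uniform +-1 h jitter to late scans.
#' @param drop_blood_sample drop one 90-h blood sample.
#' @return A [CohortConfig-class].
#' @examples
#' CohortConfig(seed = 42)
#' @export
CohortConfig <- function(n_patients = 6L,
                         patient_ids = c("1", "2", "3", "6", "9", "10"),
                         arm_assignment = c(`1` = 604, `2` = 604, `3` = 604,
                                            `6` = 44, `9` = 44, `10` = 44),
                         scan_times_c1 = c(2, 90, 138),
                         scan_times_c2 = c(90, 138),
                         blood_times_c1 = c(1, 2, 90, 138),
                         blood_times_c2 = c(1, 90, 138),
                         lesions_min = 2L, lesions_max = 5L,
                         noise_cv = 0.1, seed = 1L,
                         injected_activity = 37, tracer_mass = 4,
                         scan_jitter = FALSE, drop_blood_sample = FALSE) {
  if (n_patients != 6L && identical(patient_ids, c("1", "2", "3", "6", "9", "10"))) {
    patient_ids <- as.character(seq_len(n_patients))
    arm_assignment <- stats::setNames(rep(c(604, 44), length.out = n_patients),
                                      patient_ids)
  }
  new("CohortConfig", n_patients = as.integer(n_patients),
      patient_ids = patient_ids, arm_assignment = arm_assignment,
      scan_times_c1 = scan_times_c1, scan_times_c2 = scan_times_c2,
      blood_times_c1 = blood_times_c1, blood_times_c2 = blood_times_c2,
      lesions_min = as.integer(lesions_min), lesions_max = as.integer(lesions_max),
      noise_cv = noise_cv, seed = as.integer(seed),
      injected_activity = injected_activity, tracer_mass = tracer_mass,
      scan_jitter = scan_jitter, drop_blood_sample = drop_blood_sample)
}

#' Multiplicative measurement noise
#'
#' Multiplies each sample by `(1 + eps)` with `eps ~ Normal(0, cv)`,
#' truncated at -0.99 so that positive values stay positive.  With a seed
#' the draw is reproducible and the caller's RNG state is untouched.
#'
#' @param tac a [TimeActivityCurve-class].
#' @param cv fractional standard deviation (>= 0).
#' @param seed optional integer seed.
#' @return A [TimeActivityCurve-class] with perturbed concentrations.
#' @examples
#' tac <- TimeActivityCurve("spleen", c(2, 90), c(5, 4))
#' addNoise(tac, 0.1, seed = 7)
#' @export
addNoise <- function(tac, cv, seed = NULL) {
  stopifnot(is(tac, "TimeActivityCurve"))
  if (cv < 0) stop("cv must be >= 0")
  if (cv == 0) return(tac)
  conc <- if (is.null(seed)) {
    .noisyValues(tacConc(tac), cv)
  } else {
    .withSeed(seed, .noisyValues(tacConc(tac), cv))
  }
  initialize(tac, conc = conc)
}

.noisyValues <- function(x, cv) {
  x * (1 + pmax(stats::rnorm(length(x), 0, cv), -0.99))
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.configHash <- function(config) {
  ## dependency-free FNV-1a style hash of the serialized configuration
  raw <- as.integer(serialize(lapply(slotNames(config), slot, object = config),
                              NULL))
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Generate a synthetic imaging cohort
#'
#' Draws a cohort from the calibrated generative model: per-patient plasma
#' kinetics (log-normal variability on the amplitudes, mean-preserving, and
#' on the terminal clearance), per-lesion immune infiltration driving a
#' log-normal specific-Ki distribution (with perfusion coupled to the same
#' latent scale), saturable uptake through the dose-occupancy model, organ
#' curves from the calibrated organ parameter sets with patient-level
#' log-normal variability of the specific component, simulated LAG-3
#' immunohistochemistry (binomial sampling of positive cells), and
#' multiplicative measurement noise.  The result is a pure function of the
#' configuration (which includes the seed).
#'
#' Observed plasma samples are decay-corrected \%IA/L (well-counter
#' convention); observed region samples are image-space Bq/mL \emph{without}
#' decay correction, so the quantification pipeline is genuinely exercised.
#'
#' @param config a [CohortConfig-class].
#' @return A [PETCohort-class].
#' @examples
#' coh <- generateCohort(CohortConfig(seed = 11))
#' coh
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  .withSeed(config@seed, .generateCohortImpl(config))
}

.generateCohortImpl <- function(config) {
  ref <- referenceCohortSummaries()
  tumor_cal <- calibrateTumorModel()
  occ_cal <- .memo("occ_cal", calibrateOccupancy)
  organs <- defaultOrganParams()
  ia_bq <- config@injected_activity * 1e6
  half_life <- zr89HalfLife()

  plasma_rows <- list(); tac_rows <- list(); inj_rows <- list()
  lesion_rows <- list(); plasma_truth <- list(); organ_truth <- list()
  patient_rows <- list()

  ## observed Bq/mL (image space): un-correct decay and convert from %IA/L
  toMeasured <- function(pct_ial, t) {
    decayUncorrect(pct_ial * ia_bq / 1e5, t, half_life)
  }
  noisy <- function(x) {
    if (config@noise_cv == 0) x else .noisyValues(x, config@noise_cv)
  }

  for (p in seq_len(config@n_patients)) {
    pid <- config@patient_ids[p]
    dose2 <- unname(config@arm_assignment[[pid]])
    weight <- exp(stats::rnorm(1, log(75), 0.15))
    amp_f <- exp(stats::rnorm(1, -0.45^2 / 2, 0.45))   # mean-1 log-normal
    cl_f <- exp(stats::rnorm(1, 0, 0.15))              # median-1 log-normal
    patient_rows[[p]] <- data.frame(patient_id = pid, weight_kg = weight,
                                    amp_factor = amp_f, clearance_factor = cl_f,
                                    cycle2_dose_mg = dose2)
    ## patient-level organ kinetic scale (specific component only)
    worg <- stats::setNames(exp(stats::rnorm(length(organs), 0, 0.3)),
                            names(organs))
    ## lesions
    n_les <- sample(seq(config@lesions_min, config@lesions_max), 1)
    u <- stats::runif(n_les)
    w <- exp(tumor_cal$sigma_w * stats::qnorm(u))
    vol <- pmin(pmax(exp(stats::rnorm(n_les, log(12), 0.75)), 3), 120)
    site <- sample(c("lymph-node", "other"), n_les, replace = TRUE,
                   prob = c(0.4, 0.6))
    n_cells <- 100 + stats::rpois(n_les, 150)
    ihc <- 100 * stats::rbinom(n_les, n_cells, 0.32 * u^1.5) / n_cells
    tp <- tumor_cal$params
    les_par <- lapply(seq_len(n_les), function(j) {
      ks <- tumor_cal$ki_spec_median * w[j]
      k1 <- tp@k1 * w[j]^tumor_cal$gamma
      ## extreme lesions stay below the delivery limit 1000*k1
      ks <- min(ks, 0.95 * 1000 * k1)
      TissueKineticParams(vb = tp@vb * w[j]^tumor_cal$gamma, k1 = k1,
                          k2 = tp@k2, k3_max = .k3ForKiSpec(ks, k1, tp@k2),
                          ki_nonspec = tp@ki_nonspec)
    })
    lesion_rows[[p]] <- data.frame(
      patient_id = pid,
      lesion_id = sprintf("P%s_L%d", pid, seq_len(n_les)),
      volume_ml = vol, site_class = site, infiltration = u,
      ki_spec_unblocked = tumor_cal$ki_spec_median * w,
      ihc_lag3_pct = ihc,
      vb = vapply(les_par, slot, 0, name = "vb"),
      k1 = vapply(les_par, slot, 0, name = "k1"),
      k2 = vapply(les_par, slot, 0, name = "k2"),
      k3_max = vapply(les_par, slot, 0, name = "k3_max"),
      ki_nonspec = vapply(les_par, slot, 0, name = "ki_nonspec"))

    for (cyc in 1:2) {
      dose <- if (cyc == 1) config@tracer_mass else dose2
      base <- plasmaModelForDose(if (cyc == 1) 4 else dose2)
      pk <- PlasmaPKParams(amp_fast = base@amp_fast * amp_f,
                           amp_slow = base@amp_slow * amp_f,
                           lambda_fast = base@lambda_fast,
                           lambda_slow = base@lambda_slow,
                           clearance_scale = base@clearance_scale * cl_f)
      plasma_truth[[length(plasma_truth) + 1L]] <- data.frame(
        patient_id = pid, cycle = cyc, mass_dose_mg = dose,
        amp_fast = pk@amp_fast, amp_slow = pk@amp_slow,
        lambda_fast = pk@lambda_fast, lambda_slow = pk@lambda_slow,
        clearance_scale = pk@clearance_scale)
      inj_rows[[length(inj_rows) + 1L]] <- data.frame(
        patient_id = pid, cycle = cyc, activity_mbq = config@injected_activity,
        mass_mg = dose, weight_kg = weight,
        t0_iso8601 = sprintf("2020-0%d-01T10:00:00Z", cyc))
      ## blood / plasma samples (well counter: decay-corrected %IA/L)
      bt <- if (cyc == 1) config@blood_times_c1 else config@blood_times_c2
      if (config@drop_blood_sample && cyc == 2 && p == 1)
        bt <- bt[abs(bt - 90) > 1]
      cp <- tacConc(simulatePlasmaCurve(pk, bt))
      plasma_rows[[length(plasma_rows) + 1L]] <- data.frame(
        patient_id = pid, cycle = cyc, time_h = bt,
        conc_pct_ia_per_l = noisy(cp))
      ## scan times
      st <- if (cyc == 1) config@scan_times_c1 else config@scan_times_c2
      if (config@scan_jitter) {
        late <- st > 24
        st[late] <- st[late] + stats::runif(sum(late), -1, 1)
      }
      occ_organ <- receptorOccupancy(dose, occ_cal$model)
      occ_tumor <- receptorOccupancy(dose, tumor_cal$occupancy)
      for (org in names(organs)) {
        pars <- organs[[org]]
        ks <- 1000 * pars@k1 * pars@k3_max / (pars@k2 + pars@k3_max) *
          worg[[org]]
        pars2 <- TissueKineticParams(vb = pars@vb, k1 = pars@k1, k2 = pars@k2,
                                     k3_max = if (ks > 0)
                                       .k3ForKiSpec(min(ks, 950 * pars@k1),
                                                    pars@k1, pars@k2) else 0,
                                     ki_nonspec = pars@ki_nonspec)
        tac <- simulateTissueCurve(pars2, occ_organ, pk, st,
                                   region_id = org, cycle = cyc)
        tac_rows[[length(tac_rows) + 1L]] <- data.frame(
          patient_id = pid, region_id = org, region_type = "organ",
          cycle = cyc, time_h = st,
          conc_bq_per_ml = noisy(toMeasured(tacConc(tac), st)))
        if (cyc == 1)
          organ_truth[[length(organ_truth) + 1L]] <- data.frame(
            patient_id = pid, organ = org, scale = worg[[org]],
            ki_eff_4mg = effectiveKi(pars2, occ_organ),
            ki_eff_44mg = effectiveKi(pars2, receptorOccupancy(44, occ_cal$model)),
            ki_eff_604mg = effectiveKi(pars2, receptorOccupancy(604, occ_cal$model)))
      }
      for (j in seq_len(n_les)) {
        lid <- sprintf("P%s_L%d", pid, j)
        tac <- simulateTissueCurve(les_par[[j]], occ_tumor, pk, st,
                                   region_id = lid, region_type = "tumor",
                                   cycle = cyc)
        tac_rows[[length(tac_rows) + 1L]] <- data.frame(
          patient_id = pid, region_id = lid, region_type = "tumor",
          cycle = cyc, time_h = st,
          conc_bq_per_ml = noisy(toMeasured(tacConc(tac), st)))
      }
    }
  }
  new("PETCohort", config = config,
      injections = do.call(rbind, inj_rows),
      plasma = do.call(rbind, plasma_rows),
      tac = do.call(rbind, tac_rows),
      lesions = do.call(rbind, lesion_rows),
      truth = list(plasma_params = do.call(rbind, plasma_truth),
                   organ_params = do.call(rbind, organ_truth),
                   patients = do.call(rbind, patient_rows),
                   occupancy = list(organ = occ_cal$model,
                                    tumor = tumor_cal$occupancy)),
      provenance = list(seed = config@seed, config_hash = .configHash(config)))
}

#' Write / read a cohort as a directory of plain-text files
#'
#' `writeCohort` writes `cohort.json` (configuration, seed, ground truth)
#' plus RFC-4180 CSV tables `plasma.csv`, `tac.csv`, `injections.csv` and
#' `lesions.csv`; `readCohort` reconstructs the [PETCohort-class].
#'
#' @param cohort a [PETCohort-class].
#' @param dir directory to create/read.
#' @return `writeCohort` returns `dir` invisibly; `readCohort` a
#'   [PETCohort-class].
#' @examples
#' d <- file.path(tempdir(), "coh")
#' writeCohort(generateCohort(CohortConfig(seed = 3)), d)
#' readCohort(d)
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "PETCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- cohort@config
  cfg_list <- stats::setNames(lapply(slotNames(cfg), slot, object = cfg),
                              slotNames(cfg))
  cfg_list$arm_assignment <- as.list(cfg@arm_assignment)  # keep names in JSON
  truth <- cohort@truth
  truth$occupancy <- lapply(truth$occupancy, function(m)
    list(d50 = m@d50, hill = m@hill))
  jsonlite::write_json(
    list(config = cfg_list, provenance = cohort@provenance, truth = truth),
    file.path(dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(cohort@plasma, file.path(dir, "plasma.csv"), row.names = FALSE)
  utils::write.csv(cohort@tac, file.path(dir, "tac.csv"), row.names = FALSE)
  utils::write.csv(cohort@injections, file.path(dir, "injections.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort@lesions, file.path(dir, "lesions.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  cfgl <- meta$config
  cfg <- CohortConfig(
    n_patients = cfgl$n_patients, patient_ids = cfgl$patient_ids,
    arm_assignment = stats::setNames(unlist(cfgl$arm_assignment),
                                     names(cfgl$arm_assignment)),
    scan_times_c1 = cfgl$scan_times_c1, scan_times_c2 = cfgl$scan_times_c2,
    blood_times_c1 = cfgl$blood_times_c1, blood_times_c2 = cfgl$blood_times_c2,
    lesions_min = cfgl$lesions_min, lesions_max = cfgl$lesions_max,
    noise_cv = cfgl$noise_cv, seed = cfgl$seed,
    injected_activity = cfgl$injected_activity, tracer_mass = cfgl$tracer_mass,
    scan_jitter = cfgl$scan_jitter, drop_blood_sample = cfgl$drop_blood_sample)
  truth <- meta$truth
  truth$occupancy <- list(
    organ = OccupancyModel(d50 = truth$occupancy$organ$d50,
                           hill = truth$occupancy$organ$hill),
    tumor = OccupancyModel(d50 = truth$occupancy$tumor$d50,
                           hill = truth$occupancy$tumor$hill))
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    colClasses = c(patient_id = "character"))
  new("PETCohort", config = cfg,
      injections = rd("injections.csv"), plasma = rd("plasma.csv"),
      tac = rd("tac.csv"), lesions = rd("lesions.csv"),
      truth = truth, provenance = meta$provenance)
}
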