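## Configuration, schema validation and the end-to-end pipeline.

.schemaColumns <- list(
  plasma = c(patient_id = "character", cycle = "numeric", time_h = "numeric",
             conc_pct_ia_per_l = "numeric"),
  tac = c(patient_id = "character", region_id = "character",
          region_type = "character", cycle = "numeric", time_h = "numeric",
          conc_bq_per_ml = "numeric"),
  injections = c(patient_id = "character", cycle = "numeric",
                 activity_mbq = "numeric", mass_mg = "numeric",
                 weight_kg = "numeric", t0_iso8601 = "character"),
  lesions = c(patient_id = "character", lesion_id = "character",
              volume_ml = "numeric", site_class = "character",
              infiltration = "numeric", ki_spec_unblocked = "numeric",
              ihc_lag3_pct = "numeric"),
  uptake = c(patient_id = "character", region_id = "character",
             region_type = "character", cycle = "numeric",
             mass_dose_mg = "numeric", time_h = "numeric",
             measure_kind = "character", value = "numeric"),
  patlak = c(patient_id = "character", region_id = "character",
             region_type = "character", cycle = "numeric",
             mass_dose_mg = "numeric", ki_ul_g_h = "numeric",
             v_intercept = "numeric", r_squared = "numeric",
             n_points = "numeric")
)

#' Validate a pipeline CSV against its schema
#'
#' Checks the header, column types, value constraints (non-negative
#' concentrations and times) and, for time-resolved tables, strictly
#' increasing times within each region series.  Content problems are
#' returned as a character vector of messages naming file, row and column;
#' an unreadable file is the only condition that throws.
#'
#' @param file path to a CSV file.
#' @param schema_id one of `"plasma"`, `"tac"`, `"injections"`,
#'   `"lesions"`, `"uptake"`, `"patlak"`.
#' @return character vector of errors; `character(0)` means pass.
#' @examples
#' d <- file.path(tempdir(), "coh_vs")
#' writeCohort(generateCohort(CohortConfig(seed = 8)), d)
#' validateSchema(file.path(d, "tac.csv"), "tac")
#' @export
validateSchema <- function(file, schema_id) {
  schema <- .schemaColumns[[schema_id]]
  if (is.null(schema)) stop("unknown schema_id: ", schema_id)
  if (!file.exists(file)) stop("file not found: ", file)
  errs <- character()
  d <- tryCatch(utils::read.csv(file, colClasses = "character"),
                error = function(e) NULL)
  if (is.null(d) || !ncol(d))
    return(sprintf("%s: unreadable or missing header", basename(file)))
  fn <- basename(file)
  missing <- setdiff(names(schema), names(d))
  if (length(missing))
    return(sprintf("%s: missing column(s) %s", fn,
                   paste(missing, collapse = ", ")))
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(d[[col]]))
      bad <- which(is.na(v) & !(d[[col]] %in% c("NA", "")))
      if (length(bad))
        errs <- c(errs, sprintf("%s: row %d, column %s: not numeric (%s)",
                                fn, bad[1], col, d[[col]][bad[1]]))
      d[[col]] <- v
    }
  }
  for (col in intersect(c("time_h", "conc_pct_ia_per_l", "conc_bq_per_ml",
                          "activity_mbq", "weight_kg", "volume_ml", "value"),
                        names(d))) {
    bad <- which(!is.na(d[[col]]) & d[[col]] < 0)
    if (length(bad))
      errs <- c(errs, sprintf("%s: row %d, column %s: negative value (%g)",
                              fn, bad[1], col, d[[col]][bad[1]]))
  }
  if (schema_id %in% c("plasma", "tac") && !length(errs)) {
    keycols <- intersect(c("patient_id", "region_id", "cycle"), names(d))
    key <- do.call(paste, d[keycols])
    for (k in unique(key)) {
      tt <- d$time_h[key == k]
      if (any(diff(tt) <= 0))
        errs <- c(errs, sprintf("%s: non-increasing time for series '%s'", fn, k))
    }
  }
  errs
}

#' Read and validate a pipeline configuration
#'
#' Configurations are JSON or YAML with keys `out_dir`, `seed`, `cohort`
#' (arguments of [CohortConfig()]), `quantification` (`half_life`,
#' `tolerance_h`), `patlak` (`window`, `input_model`), `comparison`
#' (`time_h`, `style`, `cluster`) and `immune` (`threshold`); unknown keys
#' are rejected.  Missing sections fall back to package defaults.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return validated configuration list (with a `version` stamp).
#' @examples
#' p <- file.path(tempdir(), "cfg.json")
#' jsonlite::write_json(list(seed = 7), p, auto_unbox = TRUE)
#' readPipelineConfig(p)$seed
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .validatePipelineConfig(cfg)
}

.validatePipelineConfig <- function(cfg) {
  known <- c("out_dir", "input_dir", "seed", "cohort", "quantification",
             "patlak", "comparison", "immune", "version")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  sub_known <- list(
    cohort = names(formals(CohortConfig)),
    quantification = c("half_life", "tolerance_h"),
    patlak = c("window", "input_model"),
    comparison = c("time_h", "style", "cluster"),
    immune = c("threshold"))
  for (sec in names(sub_known)) {
    unknown <- setdiff(names(cfg[[sec]]), sub_known[[sec]])
    if (length(unknown))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(unknown, collapse = ", ")))
  }
  cfg$version <- as.character(utils::packageVersion("ImmunoPatlak"))
  cfg
}

#' Run the end-to-end pipeline
#'
#' Executes the stages in order -- simulate (or load and validate input
#' tables), quantify, Patlak, dose comparison, immune summary -- writes all
#' CSV/JSON outputs plus a human-readable `report.txt`, and returns a run
#' manifest (config hash, seed, software version, per-stage row counts).
#' The run is idempotent for a fixed configuration and seed.
#'
#' @param config configuration list (see [readPipelineConfig()]) or a path
#'   to a JSON/YAML configuration file.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param seed seed (overrides `config$seed`).
#' @return the manifest, invisibly; outputs are written to `out_dir`.
#' @examples
#' man <- runPipeline(list(seed = 42), out_dir = file.path(tempdir(), "run42"))
#' man$rows
#' @export
runPipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- .validatePipelineConfig(config)
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (is.null(config$out_dir)) stop("an output directory is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logmsg <- function(stage, ...)
    message(sprintf("[%s] %s", stage, sprintf(...)))

  ## -- simulate / load --
  if (!is.null(config$input_dir)) {
    logmsg("load", "reading cohort from %s", config$input_dir)
    for (f in c("plasma", "tac", "injections", "lesions")) {
      errs <- validateSchema(file.path(config$input_dir,
                                       paste0(f, ".csv")), f)
      if (length(errs))
        stop("stage 'quantify' input validation failed: ",
             paste(errs, collapse = "; "))
    }
    cohort <- readCohort(config$input_dir)
  } else {
    cargs <- config$cohort
    if (!is.null(config$seed)) cargs$seed <- config$seed
    cohort <- generateCohort(do.call(CohortConfig, as.list(cargs)))
    logmsg("simulate", "%d patients, %d lesions",
           cohort@config@n_patients, nrow(cohort@lesions))
    writeCohort(cohort, config$out_dir)
  }

  ## -- quantify --
  qa <- config$quantification
  uptake <- uptakeTable(cohort,
                        tolerance_h = if (is.null(qa$tolerance_h)) 6
                                      else qa$tolerance_h,
                        half_life = if (is.null(qa$half_life)) zr89HalfLife()
                                    else qa$half_life)
  utils::write.csv(uptake, file.path(config$out_dir, "uptake.csv"),
                   row.names = FALSE)
  logmsg("quantify", "%d uptake rows", nrow(uptake))

  ## -- patlak --
  pa <- config$patlak
  pat <- patlakTable(cohort,
                     window = if (is.null(pa$window)) c(24, Inf)
                              else as.numeric(pa$window),
                     input_model = if (is.null(pa$input_model))
                       "biexponential" else pa$input_model)
  utils::write.csv(pat, file.path(config$out_dir, "patlak.csv"),
                   row.names = FALSE)
  logmsg("patlak", "%d fits", nrow(pat))

  ## -- compare --
  ca <- config$comparison
  cmp <- compareDoseGroups(
    uptake, time_h = if (is.null(ca$time_h)) 138 else ca$time_h,
    style = if (is.null(ca$style)) "nonparametric" else ca$style,
    cluster = if (is.null(ca$cluster)) "lesion" else ca$cluster)
  summaries <- do.call(rbind, lapply(names(cmp$groups), function(d)
    cbind(dose = d, summarizeGroup(cmp$groups[[d]], "nonparametric"))))
  utils::write.csv(summaries, file.path(config$out_dir, "summaries.csv"),
                   row.names = FALSE)
  spleen_ki <- pat[pat$region_id == "spleen", ]
  ki_by_dose <- vapply(split(spleen_ki$ki_ul_g_h, spleen_ki$mass_dose_mg),
                       mean, 0)
  sat <- if (all(c("4", "604") %in% names(ki_by_dose)) &&
             ki_by_dose[["4"]] > ki_by_dose[["604"]])
    saturationReport(ki_by_dose, "4", "604") else NULL
  jsonlite::write_json(
    list(comparison = cmp[setdiff(names(cmp), "groups")],
         saturation = sat, seed = config$seed),
    file.path(config$out_dir, "comparisons.json"), auto_unbox = TRUE,
    digits = NA, force = TRUE)
  logmsg("compare", "global p = %.3g", cmp$p_global)

  ## -- immune --
  im <- immuneSummary(cohort, uptake,
                      threshold = if (is.null(config$immune$threshold)) 3.0
                                  else config$immune$threshold)
  utils::write.csv(im, file.path(config$out_dir, "immune.csv"),
                   row.names = FALSE)
  logmsg("immune", "%d desert / %d infiltrated",
         sum(im$phenotype == "desert"), sum(im$phenotype == "infiltrated"))

  ## -- report + manifest --
  rep <- c(
    "Immuno-PET mass-dose pipeline report",
    sprintf("seed %d, config hash %s", cohort@provenance$seed,
            cohort@provenance$config_hash),
    "",
    "Tumor-to-plasma summaries (median [IQR]):",
    sprintf("  %s mg: %.2f [%.2f-%.2f] (n=%d)", summaries$dose,
            summaries$central, summaries$spread_lo, summaries$spread_hi,
            summaries$n),
    "",
    if (!is.null(sat)) c("Spleen saturation:",
      sprintf("  %s mg: Ki %.2f uL/g/h, %.0f%% blocked (%s)", sat$dose,
              sat$ki, 100 * sat$fraction_blocked, sat$classification), "")
    else "Spleen saturation: not computable on this run",
    "Immune phenotypes:",
    sprintf("  patient %s: ratio %.2f -> %s", im$patient_id,
            im$mean_ratio_138h, im$phenotype))
  writeLines(rep, file.path(config$out_dir, "report.txt"))
  manifest <- list(
    version = config$version, seed = cohort@provenance$seed,
    config_hash = cohort@provenance$config_hash,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    rows = list(plasma = nrow(cohort@plasma), tac = nrow(cohort@tac),
                injections = nrow(cohort@injections),
                lesions = nrow(cohort@lesions), uptake = nrow(uptake),
                patlak = nrow(pat), immune = nrow(im)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
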