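## Group summaries, mass-dose comparisons and saturation metrics.

#' Summarize one dose group
#'
#' Parametric summaries are mean with sample standard deviation (n-1
#' denominator); nonparametric summaries are median with interquartile
#' range using linear-interpolation quantiles.  Study convention: organs
#' and plasma are summarized parametrically, tumor lesions
#' nonparametrically.
#'
#' @param values numeric vector (n >= 1).
#' @param style `"parametric"` or `"nonparametric"`.
#' @return one-row data.frame with n, central, spread_lo, spread_hi.
#' @examples
#' summarizeGroup(c(1, 2, 3, 4, 5), "nonparametric")  # median 3, IQR 2--4
#' @export
summarizeGroup <- function(values, style = c("nonparametric", "parametric")) {
  style <- match.arg(style)
  if (!length(values)) stop("empty input")
  if (style == "parametric") {
    s <- if (length(values) > 1) stats::sd(values) else 0
    data.frame(n = length(values), central = mean(values),
               spread_lo = mean(values) - s, spread_hi = mean(values) + s,
               style = style)
  } else {
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(n = length(values), central = q[2],
               spread_lo = q[1], spread_hi = q[3], style = style)
  }
}

.pairGroups <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(!vapply(groups, length, 1L))) stop("every group must be non-empty")
  utils::combn(names(groups), 2, simplify = FALSE)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' The parametric comparison used for plasma activity concentrations
#' across mass-dose arms: global one-way ANOVA (F, between-group df)
#' followed by Tukey honestly-significant-difference adjusted pairwise
#' comparisons.  Unbalanced groups are supported.
#'
#' @param groups named list of numeric vectors (dose arms).
#' @return list with `test`, `global_stat` (F), `df` (between, within),
#'   `p_global`, and `pairwise` data.frame (pair, statistic = mean
#'   difference, p_raw (NA for Tukey), p_adjusted), `alpha`.
#' @examples
#' compareParametric(list(`4` = c(5, 7, 6), `604` = c(13, 15, 16)))
#' @export
compareParametric <- function(groups) {
  pairs <- .pairGroups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(values) <= length(groups))
    stop("total n must exceed the number of groups")
  if (stats::var(values) == 0)
    stop("all values identical across groups: F undefined")
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    key <- paste(pr[2], pr[1], sep = "-")
    if (!key %in% rownames(tk)) key <- paste(pr[1], pr[2], sep = "-")
    data.frame(pair = paste(pr, collapse = " vs "),
               statistic = tk[key, "diff"], p_raw = NA_real_,
               p_adjusted = tk[key, "p adj"])
  }))
  list(test = "anova_tukey", global_stat = an$`F value`[1],
       df = c(between = an$Df[1], within = an$Df[2]),
       p_global = an$`Pr(>F)`[1], pairwise = pw, alpha = 0.05)
}

#' Kruskal-Wallis with pairwise Wilcoxon rank-sum tests
#'
#' The nonparametric comparison used for lesion-level tumor-to-plasma
#' ratios across mass-dose arms: global Kruskal-Wallis (tie-corrected H)
#' followed by two-sided pairwise Wilcoxon rank-sum tests -- exact when the
#' smaller group has at most 10 observations and there are no ties, normal
#' approximation with mid-ranks otherwise -- Bonferroni-adjusted over all
#' pairs.
#'
#' @param groups named list of numeric vectors.
#' @return list with `test`, `global_stat` (H), `df`, `p_global`,
#'   `pairwise` data.frame (pair, statistic = rank-sum W, p_raw,
#'   p_adjusted), `alpha`.
#' @examples
#' compareNonparametric(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
compareNonparametric <- function(groups) {
  pairs <- .pairGroups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kw <- stats::kruskal.test(values, g)
  m <- length(pairs)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    x <- groups[[pr[1]]]; y <- groups[[pr[2]]]
    exact <- min(length(x), length(y)) <= 10 && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = !exact))
    data.frame(pair = paste(pr, collapse = " vs "),
               statistic = unname(wt$statistic), p_raw = wt$p.value,
               p_adjusted = min(1, m * wt$p.value))
  }))
  list(test = "kw_wilcoxon_bonferroni", global_stat = unname(kw$statistic),
       df = unname(kw$parameter), p_global = kw$p.value, pairwise = pw,
       alpha = 0.05)
}

#' Saturation metrics across mass doses
#'
#' Quantifies how much of the target-specific signal is blocked at each
#' dose: `fraction_blocked(d) = 1 - (Ki_d - Ki_floor) / (Ki_ref - Ki_floor)`
#' relative to the unblocked reference dose and the fully-blocked floor
#' dose.  Classification: `full` when at least `full_at`, `partial` when at
#' least `partial_at`, `none` below.
#'
#' @param ki_by_dose named numeric, Ki (or ratio) by mass dose.
#' @param ref_dose name of the unblocked reference dose.
#' @param floor_dose name of the fully-blocked dose.
#' @param full_at,partial_at classification thresholds on the blocked
#'   fraction.
#' @return data.frame: dose, ki, fraction_blocked, classification.
#' @examples
#' saturationReport(c(`4` = 30.06, `44` = 2.91, `604` = 0.67), "4", "604")
#' @export
saturationReport <- function(ki_by_dose, ref_dose, floor_dose,
                             full_at = 0.95, partial_at = 0.5) {
  stopifnot(ref_dose %in% names(ki_by_dose),
            floor_dose %in% names(ki_by_dose))
  ref <- ki_by_dose[[ref_dose]]; floor <- ki_by_dose[[floor_dose]]
  if (ref <= floor) stop("Ki at the reference dose must exceed the floor")
  frac <- 1 - (ki_by_dose - floor) / (ref - floor)
  cls <- ifelse(frac >= full_at, "full",
                ifelse(frac >= partial_at, "partial", "none"))
  data.frame(dose = names(ki_by_dose), ki = unname(ki_by_dose),
             fraction_blocked = unname(frac), classification = unname(cls))
}

#' Compare mass-dose arms on a cohort uptake table
#'
#' Builds the dose groups for a given measure and time point --
#' the tracer-only dose from cycle 1, the escalated doses from cycle 2 --
#' and runs the appropriate comparison.  Lesions are treated as independent
#' observations by default (the study pools lesions across patients); a
#' patient-clustered sensitivity mode averages lesions within a patient
#' first.
#'
#' @param uptake data.frame from [uptakeTable()].
#' @param time_h time point to compare, h.
#' @param region_type `"tumor"` or `"organ"` (optionally with `region_id`).
#' @param region_id optional single region for organ comparisons.
#' @param measure_kind measure to compare.
#' @param style `"nonparametric"` (lesions) or `"parametric"`.
#' @param cluster `"lesion"` (pool lesions) or `"patient"` (per-patient
#'   means).
#' @param time_tol pairing tolerance on `time_h`, h.
#' @return list as returned by [compareNonparametric()] /
#'   [compareParametric()], plus `groups` (the values used).
#' @examples
#' up <- uptakeTable(generateCohort(CohortConfig(seed = 5)))
#' compareDoseGroups(up)$pairwise
#' @export
compareDoseGroups <- function(uptake, time_h = 138, region_type = "tumor",
                              region_id = NULL,
                              measure_kind = "tissue_to_plasma",
                              style = c("nonparametric", "parametric"),
                              cluster = c("lesion", "patient"),
                              time_tol = 3) {
  style <- match.arg(style); cluster <- match.arg(cluster)
  sel <- uptake$measure_kind == measure_kind &
    abs(uptake$time_h - time_h) <= time_tol &
    uptake$region_type == region_type
  if (!is.null(region_id)) sel <- sel & uptake$region_id == region_id
  d <- uptake[sel, ]
  if (!nrow(d)) stop("no rows match the requested comparison")
  if (cluster == "patient") {
    agg <- stats::aggregate(value ~ patient_id + mass_dose_mg, d, mean)
    groups <- split(agg$value, agg$mass_dose_mg)
  } else {
    groups <- split(d$value, d$mass_dose_mg)
  }
  groups <- groups[order(as.numeric(names(groups)))]
  res <- if (style == "nonparametric") compareNonparametric(groups)
         else compareParametric(groups)
  res$groups <- groups
  res
}
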