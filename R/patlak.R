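## Plasma input-function fitting and Patlak graphical analysis.

.interpRate0 <- function(p) {
  ## extrapolation rate towards t = 0 for the log-linear interpolant:
  ## the first segment's rate (flat if only one knot)
  if (length(p$knot_t) < 2) 0 else -diff(log(p$knot_c[1:2])) / diff(p$knot_t[1:2])
}

#' Evaluate a fitted input function
#'
#' @param input a [PlasmaPKParams-class] or [InputFunctionFit-class].
#' @param times hours post injection (>= 0).
#' @return plasma concentration at `times`, \%IA/L.
#' @examples
#' fit <- fitInputFunction(simulatePlasmaCurve(plasmaModelForDose(4),
#'                                             c(1, 2, 90, 138)))
#' inputConc(fit, 90)
#' @export
inputConc <- function(input, times) {
  if (any(times < 0)) stop("times must be >= 0")
  if (is(input, "PlasmaPKParams")) {
    tm <- .plasmaTerms(input)
    return(.biexpEval(times, tm$A, tm$l))
  }
  stopifnot(is(input, "InputFunctionFit"))
  p <- input@params
  if (input@model == "biexponential")
    return(.biexpEval(times, c(p$A1, p$A2), c(p$l1, p$l2)))
  kt <- p$knot_t; kc <- p$knot_c
  mu <- .segmentRates(kt, kc)
  r0 <- .interpRate0(p)
  vapply(times, function(t) {
    if (t <= kt[1]) return(kc[1] * exp(r0 * (kt[1] - t)))
    s <- findInterval(t, kt)
    kc[s] * exp(-mu[s] * (t - kt[s]))
  }, 0)
}

#' Exact time integral of a fitted input function
#'
#' Closed-form \eqn{\int_0^t C_p(\tau)\, d\tau} for the bi-exponential
#' model, or the exact piecewise-exponential integral for the log-linear
#' interpolant.
#'
#' @inheritParams inputConc
#' @return integral values, \%IA/L * h.
#' @examples
#' inputIntegral(plasmaModelForDose(4), c(90, 138))
#' @export
inputIntegral <- function(input, times) {
  if (any(times < 0)) stop("times must be >= 0")
  if (is(input, "PlasmaPKParams")) {
    tm <- .plasmaTerms(input)
    return(.biexpIntegral(times, tm$A, tm$l))
  }
  stopifnot(is(input, "InputFunctionFit"))
  p <- input@params
  if (input@model == "biexponential")
    return(.biexpIntegral(times, c(p$A1, p$A2), c(p$l1, p$l2)))
  kt <- p$knot_t; kc <- p$knot_c
  mu <- .segmentRates(kt, kc)
  r0 <- .interpRate0(p)
  segInt <- function(c0, rate, tau) {
    if (abs(rate) < 1e-12) c0 * tau else c0 * (1 - exp(-rate * tau)) / rate
  }
  ## cumulative integral at the knots
  knot_int <- numeric(length(kt))
  knot_int[1] <- segInt(kc[1] * exp(r0 * kt[1]), r0, kt[1])
  if (length(kt) > 1)
    for (s in 2:length(kt))
      knot_int[s] <- knot_int[s - 1] + segInt(kc[s - 1], mu[s - 1], kt[s] - kt[s - 1])
  vapply(times, function(t) {
    if (t <= kt[1]) return(segInt(kc[1] * exp(r0 * kt[1]), r0, t))
    s <- findInterval(t, kt)
    knot_int[s] + segInt(kc[s], mu[s], t - kt[s])
  }, 0)
}

#' Fit a continuous input function to sparse plasma samples
#'
#' Fits the plasma samples in log space.  For the bi-exponential model with
#' at least four samples, both phases are fitted by nonlinear least squares
#' (Levenberg-Marquardt, started from curve peeling); with fewer samples
#' the fast distribution phase is fixed at configured defaults and only the
#' slow phase `(A2, l2)` is fitted to the fast-phase-subtracted samples.
#' The log-linear interpolant reproduces every sample exactly at the knots.
#'
#' @param plasma a [TimeActivityCurve-class] of plasma samples (>= 2
#'   positive samples).
#' @param model `"biexponential"` (default) or `"loglinear_interp"`.
#' @param fast_amp,fast_lambda fixed fast-phase defaults used when fewer
#'   than 4 samples are available (\%IA/L and 1/h).
#' @param fix_fast force the fixed-fast-phase fit even with >= 4 samples;
#'   useful for sparse antibody sampling schedules, where the distribution
#'   phase is not identifiable and a free bi-exponential fit pins the
#'   terminal slope on the last two samples alone.
#' @return An [InputFunctionFit-class].
#' @examples
#' cp <- simulatePlasmaCurve(plasmaModelForDose(4), c(1, 2, 24, 48, 90, 138))
#' fitInputFunction(cp)
#' @export
fitInputFunction <- function(plasma, model = c("biexponential", "loglinear_interp"),
                             fast_amp = 12, fast_lambda = 0.5,
                             fix_fast = FALSE) {
  model <- match.arg(model)
  stopifnot(is(plasma, "TimeActivityCurve"))
  t <- tacTimes(plasma); y <- tacConc(plasma)
  if (length(t) < 2) stop("need at least 2 plasma samples")
  if (any(y <= 0)) stop("plasma concentrations must be positive")
  if (model == "loglinear_interp") {
    return(new("InputFunctionFit", model = "loglinear_interp",
               params = list(knot_t = t, knot_c = y), fit_residual = 0))
  }
  fit <- NULL
  if (length(t) >= 4 && !fix_fast) {
    ## start values by curve peeling: slow phase from the last two samples
    n <- length(t)
    l2_0 <- max(log(y[n - 1] / y[n]) / (t[n] - t[n - 1]), 1e-4)
    a2_0 <- y[n] * exp(l2_0 * t[n])
    a1_0 <- max(y[1] - a2_0 * exp(-l2_0 * t[1]), 0.05 * y[1])
    df <- data.frame(t = t, ly = log(y))
    fit <- tryCatch({
      m <- minpack.lm::nlsLM(
        ly ~ log(exp(la1 - exp(ll1) * t) + exp(la2 - exp(ll2) * t)),
        data = df,
        start = list(la1 = log(a1_0), ll1 = log(fast_lambda),
                     la2 = log(a2_0), ll2 = log(l2_0)),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      cf <- stats::coef(m)
      list(A1 = exp(cf[["la1"]]), l1 = exp(cf[["ll1"]]),
           A2 = exp(cf[["la2"]]), l2 = exp(cf[["ll2"]]))
    }, error = function(e) NULL)
    if (!is.null(fit) && fit$l1 < fit$l2) {  # keep fast phase first
      fit <- list(A1 = fit$A2, l1 = fit$l2, A2 = fit$A1, l2 = fit$l1)
    }
  }
  if (is.null(fit)) {
    ## fixed fast phase; log-linear OLS on the fast-subtracted samples
    resid <- y - fast_amp * exp(-fast_lambda * t)
    use <- resid > 0
    if (sum(use) < 2)
      stop("too few samples above the fixed fast phase to fit the slow phase")
    cf <- stats::lm.fit(cbind(1, -t[use]), log(resid[use]))$coefficients
    fit <- list(A1 = fast_amp, l1 = fast_lambda,
                A2 = exp(cf[1]), l2 = max(cf[2], 1e-6))
  }
  pred <- .biexpEval(t, c(fit$A1, fit$A2), c(fit$l1, fit$l2))
  new("InputFunctionFit", model = "biexponential",
      params = fit[c("A1", "l1", "A2", "l2")],
      fit_residual = sqrt(mean((pred / y - 1)^2)))
}

#' Patlak transformation
#'
#' Maps a tissue curve and an input function to Patlak coordinates
#' \eqn{x(t) = \int_0^t C_p\, d\tau / C_p(t)} (normalized time, h) and
#' \eqn{y(t) = C_t(t) / C_p(t)} (dimensionless).  For an irreversibly
#' trapped tracer the late points fall on a line with slope
#' \eqn{K_i / 1000} and intercept the reversible distribution volume.
#'
#' @param tissue a [TimeActivityCurve-class] of the region (same units as
#'   the input function, decay-corrected).
#' @param input_fit a [PlasmaPKParams-class] or [InputFunctionFit-class].
#' @return data.frame with columns `t`, `x`, `y`.
#' @examples
#' input <- plasmaModelForDose(4)
#' tac <- simulateTissueCurve(spleenParams(), 0, input, c(2, 90, 138))
#' patlakTransform(tac, input)
#' @export
patlakTransform <- function(tissue, input_fit) {
  stopifnot(is(tissue, "TimeActivityCurve"))
  t <- tacTimes(tissue)
  cp <- inputConc(input_fit, t)
  if (any(cp <= 0)) stop("input function must be positive at all tissue times")
  if (is(input_fit, "InputFunctionFit") && input_fit@model == "loglinear_interp" &&
      max(t) > max(input_fit@params$knot_t) + 1e-9)
    stop("tissue times extend beyond the input-function domain")
  data.frame(t = t, x = inputIntegral(input_fit, t) / cp,
             y = tacConc(tissue) / cp)
}

#' Ordinary-least-squares Patlak fit
#'
#' Fits `y = a + b x` to the Patlak points inside the time window and
#' reports `ki = 1000 b` (uL g^-1 h^-1, tissue density 1 g/mL), the
#' intercept and R-squared (defined as 1 when only two points are used).
#' Noise can produce negative slopes; these are reported with a
#' `"negative_slope"` flag rather than clamped, so that noise-replicate
#' statistics stay unbiased.
#'
#' @param points data.frame from [patlakTransform()].
#' @param window numeric length-2 time window (h); the default excludes the
#'   early (pre-equilibration) scan and keeps the late scans.
#' @return A [PatlakFit-class].
#' @examples
#' pts <- data.frame(t = c(90, 138), x = c(100, 200), y = 0.3 + 0.002 * c(100, 200))
#' kiValue(patlakFit(pts))  # 2 uL/g/h
#' @export
patlakFit <- function(points, window = c(24, Inf)) {
  stopifnot(all(c("t", "x", "y") %in% names(points)))
  use <- points$t >= window[1] & points$t <= window[2]
  x <- points$x[use]; y <- points$y[use]
  if (length(x) < 2) stop("need at least 2 points inside the window")
  if (max(x) - min(x) < 1e-9)
    stop("degenerate spread of Patlak abscissa inside the window")
  b <- stats::cov(x, y) / stats::var(x)
  a <- mean(y) - b * mean(x)
  ss_res <- sum((y - a - b * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (length(x) == 2L || ss_tot < 1e-300) 1 else 1 - ss_res / ss_tot
  flags <- character()
  if (b < 0) flags <- c(flags, "negative_slope")
  new("PatlakFit", ki = 1000 * b, v_intercept = a, r_squared = r2,
      n_points = length(x), window = as.numeric(window), flags = flags)
}

#' Patlak analysis of every region of a cohort
#'
#' For each patient and cycle, fits the input function to the cycle's
#' plasma samples, converts each region's measured activity to
#' decay-corrected \%IA/L, applies the Patlak transformation and fits the
#' post-equilibration window.  Organ Ki values are the reported outcome;
#' tumor-lesion Ki values are computed on simulations for completeness but
#' lack a clinical no-expression baseline, so their interpretation is
#' exploratory.
#'
#' @param cohort a [PETCohort-class].
#' @param window passed to [patlakFit()].
#' @param input_model passed to [fitInputFunction()].
#' @return data.frame with one row per region x cycle: patient_id,
#'   region_id, region_type, cycle, mass_dose_mg, ki_ul_g_h, v_intercept,
#'   r_squared, n_points, flags.
#' @examples
#' coh <- generateCohort(CohortConfig(seed = 1))
#' head(patlakTable(coh))
#' @export
patlakTable <- function(cohort, window = c(24, Inf),
                        input_model = "biexponential") {
  stopifnot(is(cohort, "PETCohort"))
  inj <- cohort@injections
  out <- list()
  for (i in seq_len(nrow(inj))) {
    pid <- inj$patient_id[i]; cyc <- inj$cycle[i]
    pl <- cohort@plasma[cohort@plasma$patient_id == pid &
                          cohort@plasma$cycle == cyc, ]
    if (nrow(pl) < 2) next
    ifit <- fitInputFunction(
      TimeActivityCurve("plasma", pl$time_h, pl$conc_pct_ia_per_l,
                        region_type = "plasma", cycle = cyc),
      model = input_model)
    tt <- cohort@tac[cohort@tac$patient_id == pid & cohort@tac$cycle == cyc, ]
    for (rid in unique(tt$region_id)) {
      rr <- tt[tt$region_id == rid, ]
      conc_ial <- percentInjectedActivity(
        decayCorrect(rr$conc_bq_per_ml, rr$time_h),
        InjectionRecord(inj$activity_mbq[i], inj$mass_mg[i],
                        inj$weight_kg[i], inj$t0_iso8601[i], cyc))
      tac <- TimeActivityCurve(rid, rr$time_h, conc_ial,
                               region_type = rr$region_type[1], cycle = cyc)
      fit <- tryCatch(patlakFit(patlakTransform(tac, ifit), window = window),
                      error = function(e) NULL)
      if (is.null(fit)) next
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, region_id = rid, region_type = rr$region_type[1],
        cycle = cyc, mass_dose_mg = inj$mass_mg[i], ki_ul_g_h = fit@ki,
        v_intercept = fit@v_intercept, r_squared = fit@r_squared,
        n_points = fit@n_points,
        flags = paste(fit@flags, collapse = ";"))
    }
  }
  do.call(rbind, out)
}
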