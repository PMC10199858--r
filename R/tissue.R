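## Irreversible two-tissue model: closed-form solution for exponential-sum
## inputs, sequential analytic propagation for piecewise-exponential inputs,
## and the calibrated default parameter sets.

.ipkEnv <- new.env(parent = emptyenv())

.memo <- function(key, fun) {
  if (is.null(.ipkEnv[[key]])) .ipkEnv[[key]] <- fun()
  .ipkEnv[[key]]
}

## (e^{-l t} - e^{-b t}) / (b - l), stable near b = l and at zero rates
.expDiff <- function(t, l, b) {
  if (abs(b - l) < 1e-9) t * exp(-l * t) else (exp(-l * t) - exp(-b * t)) / (b - l)
}

## int_0^t .expDiff(s, l, b) ds, stable near b = l and at zero rates
.expDiffInt <- function(t, l, b) {
  e1 <- function(r) if (abs(r) < 1e-12) t else (1 - exp(-r * t)) / r
  if (abs(b - l) < 1e-9) {
    if (abs(l) < 1e-12) t^2 / 2 else (1 - (1 + l * t) * exp(-l * t)) / l^2
  } else {
    (e1(l) - e1(b)) / (b - l)
  }
}

## Closed-form reversible + trapped concentrations for input sum A_i e^{-l_i t}
.tissueExpSum <- function(times, k1, k2, k3, A, l) {
  b <- k2 + k3
  crev <- numeric(length(times))
  ctrap <- numeric(length(times))
  for (i in seq_along(A)) {
    crev <- crev + k1 * A[i] * vapply(times, .expDiff, 0, l = l[i], b = b)
    ctrap <- ctrap + k1 * k3 * A[i] * vapply(times, .expDiffInt, 0, l = l[i], b = b)
  }
  list(rev = crev, trap = ctrap)
}

## Sequential analytic propagation over piecewise-exponential input segments.
## Within a segment Cp(t) = C0 e^{-mu (t - t0)}; the reversible compartment
## obeys y' = k1 Cp - b y and the trapped compartment integrates k3 y.
.tissuePiecewise <- function(times, k1, k2, k3, knot_t, knot_c, rate0) {
  b <- k2 + k3
  seg_t <- c(0, knot_t)
  seg_c <- c(knot_c[1] * exp(rate0 * knot_t[1]), knot_c)
  seg_mu <- c(rate0, .segmentRates(knot_t, knot_c))
  out_rev <- numeric(length(times)); out_trap <- numeric(length(times))
  y0 <- 0; z0 <- 0
  step <- function(tau, C0, mu, y0) {
    ## reversible value and its time-integral over [0, tau]
    conv <- vapply(tau, .expDiff, 0, l = mu, b = b)
    y <- y0 * exp(-b * tau) + k1 * C0 * conv
    iy <- y0 * (1 - exp(-b * tau)) / b +
      k1 * C0 * vapply(tau, .expDiffInt, 0, l = mu, b = b)
    list(y = y, iy = iy)
  }
  for (s in seq_along(seg_t)) {
    t_lo <- seg_t[s]
    t_hi <- if (s < length(seg_t)) seg_t[s + 1] else Inf
    sel <- times > t_lo & times <= t_hi + 1e-12
    if (any(sel)) {
      st <- step(times[sel] - t_lo, seg_c[s], seg_mu[s], y0)
      out_rev[sel] <- st$y
      out_trap[sel] <- z0 + k3 * st$iy
    }
    if (s < length(seg_t)) {
      st <- step(t_hi - t_lo, seg_c[s], seg_mu[s], y0)
      z0 <- z0 + k3 * st$iy
      y0 <- st$y
    }
  }
  zero <- times <= 1e-12
  out_rev[zero] <- 0; out_trap[zero] <- 0
  list(rev = out_rev, trap = out_trap)
}

.segmentRates <- function(knot_t, knot_c) {
  ## decay rate of each inter-knot segment of a log-linear interpolant
  mu <- -diff(log(knot_c)) / diff(knot_t)
  c(mu, mu[length(mu)])  # last segment rate extends beyond the last knot
}

.inputExpTerms <- function(input) {
  if (is(input, "PlasmaPKParams")) return(.plasmaTerms(input))
  if (is(input, "InputFunctionFit") && input@model == "biexponential") {
    p <- input@params
    return(list(A = c(p$A1, p$A2), l = c(p$l1, p$l2)))
  }
  NULL
}

#' Simulate a tissue time-activity curve
#'
#' Solves the irreversible two-tissue compartment model
#' \deqn{dC_{rev}/dt = k_1 C_p - (k_2 + k_3) C_{rev}, \qquad
#'       dC_{trap}/dt = k_3 C_{rev}}
#' and returns \eqn{C_t = C_{rev} + C_{trap} + v_b C_p} in the units of the
#' input (\%IA/L, decay-corrected).  The trapping rate \eqn{k_3} is chosen
#' so that the implied net influx rate \eqn{1000 k_1 k_3/(k_2+k_3)} equals
#' [effectiveKi()] at the given occupancy; the decay-corrected trapped
#' component is non-decreasing (residualizing label).  Exponential-sum
#' inputs are solved in closed form; piecewise log-linear inputs by exact
#' sequential propagation across segments.
#'
#' @param params a [TissueKineticParams-class].
#' @param occupancy receptor occupancy in `[0, 1]`.
#' @param input a [PlasmaPKParams-class] or [InputFunctionFit-class].
#' @param times sampling times, h post injection (>= 0).
#' @param region_id,region_type,cycle identity of the returned curve.
#' @param components if `TRUE`, return a data.frame with the blood,
#'   reversible and trapped components instead of a `TimeActivityCurve`.
#' @return A [TimeActivityCurve-class] (\%IA/L, decay-corrected), or a
#'   data.frame when `components = TRUE`.
#' @examples
#' tac <- simulateTissueCurve(spleenParams(), 0, plasmaModelForDose(4),
#'                            c(2, 90, 138))
#' tacConc(tac)
#' @export
simulateTissueCurve <- function(params, occupancy, input, times,
                                region_id = "tissue", region_type = "organ",
                                cycle = 1L, components = FALSE) {
  stopifnot(is(params, "TissueKineticParams"))
  if (any(times < 0)) stop("times must be >= 0")
  ki_eff <- effectiveKi(params, occupancy)
  terms <- .inputExpTerms(input)
  if (!is.null(terms) && any(!is.finite(c(terms$A, terms$l))))
    stop("input model parameters must be finite")
  if (params@k1 > 0) {
    q <- ki_eff / (1000 * params@k1)
    if (q >= 1) stop("effective Ki exceeds delivery limit 1000*k1")
    if (params@k2 <= 0 && q > 0) stop("k2 must be > 0 when trapping is present")
    k3 <- if (q > 0) params@k2 * q / (1 - q) else 0
  } else {
    k3 <- 0
  }
  cp <- inputConc(input, times)
  if (params@k1 > 0) {
    comp <- if (!is.null(terms)) {
      .tissueExpSum(times, params@k1, params@k2, k3, terms$A, terms$l)
    } else {
      p <- input@params
      if (max(times) > max(p$knot_t) + 1e-9)
        stop("times extend beyond the input-function domain")
      .tissuePiecewise(times, params@k1, params@k2, k3,
                       p$knot_t, p$knot_c, .interpRate0(p))
    }
  } else {
    comp <- list(rev = numeric(length(times)), trap = numeric(length(times)))
  }
  blood <- params@vb * cp
  if (components) {
    return(data.frame(time_h = times, blood = blood, reversible = comp$rev,
                      trapped = comp$trap,
                      total = blood + comp$rev + comp$trap))
  }
  TimeActivityCurve(region_id, times, blood + comp$rev + comp$trap,
                    region_type = region_type, cycle = cycle,
                    units = "%IA/L", decay_corrected = TRUE)
}

#' Calibrated spleen kinetic parameters
#'
#' Default spleen parameters: the maximal trapping rate is anchored at the
#' reported receptor re-synthesis rate (0.1 per hour), the non-specific
#' floor at the fully-blocked spleen Ki, and `k1` is chosen so that the
#' implied specific Ki equals the occupancy-calibration estimate
#' (see [calibrateOccupancy()]).
#'
#' @param k2 efflux rate, 1/h.
#' @param vb fractional blood volume.
#' @return A [TissueKineticParams-class].
#' @examples
#' spleenParams()
#' @export
spleenParams <- function(k2 = 0.2, vb = 0.25) {
  cal <- .memo("occ_cal", calibrateOccupancy)
  k3max <- referenceCohortSummaries()$receptor_synthesis_rate
  k1 <- cal$ki_spec * (k2 + k3max) / (1000 * k3max)
  TissueKineticParams(vb = vb, k1 = k1, k2 = k2, k3_max = k3max,
                      ki_nonspec = cal$ki_nonspec)
}

#' Default organ kinetic parameter sets
#'
#' Kinetic parameters for the six healthy organs carried by the cohort
#' generator.  The spleen is calibrated against the published Ki triple
#' (see [spleenParams()]); the lungs are anchored at the published low
#' lung-to-plasma ratio with no saturable component; the remaining organs
#' are synthetic but physiologically plausible defaults (hepatobiliary and
#' renal handling appear as non-specific irreversible floors, marrow
#' carries a modest saturable immune-cell component, bone a mineral-uptake
#' floor of the residualizing radiometal).
#'
#' @return named list of [TissueKineticParams-class], one per organ.
#' @examples
#' names(defaultOrganParams())
#' @export
defaultOrganParams <- function() {
  list(
    spleen = spleenParams(),
    lungs = TissueKineticParams(vb = 0.17, k1 = 0.02, k2 = 0.2, k3_max = 0,
                                ki_nonspec = 0.2),
    liver = TissueKineticParams(vb = 0.30, k1 = 0.06, k2 = 0.2, k3_max = 0.02,
                                ki_nonspec = 2.0),
    kidneys = TissueKineticParams(vb = 0.30, k1 = 0.05, k2 = 0.2, k3_max = 0.01,
                                  ki_nonspec = 1.5),
    bone_marrow = TissueKineticParams(vb = 0.20, k1 = 0.04, k2 = 0.2,
                                      k3_max = 0.05, ki_nonspec = 0.8),
    bone = TissueKineticParams(vb = 0.10, k1 = 0.01, k2 = 0.2, k3_max = 0,
                               ki_nonspec = 1.0)
  )
}

#' Calibrate the median tumor lesion against published uptake ratios
#'
#' Determines the kinetic parameters of the median tumor lesion so that the
#' simulated cohorts reproduce, as closely as the model family allows, the
#' four published lesion-level tumor-to-plasma ratio medians (4 mg at 90
#' and 138 h; 44 and 604 mg at 138 h).  `k1`, `k2` and the non-specific
#' floor are fixed at physiologic antibody values and the fractional
#' distribution volume, the median specific Ki and the tumor half-
#' saturation mass dose are fitted by deterministic least squares on the
#' log scale.  The tumor half-saturation dose is kept separate from the
#' spleen one: intratumoral antibody penetration is limited, so the
#' effective dose needed to block lesion uptake is allowed to exceed the
#' well-perfused-organ value.
#'
#' Two stages: an analytic least-squares fit of the noise-free
#' median-lesion model, followed by a simulation correction that estimates,
#' by Monte Carlo under the full generative law (patient clearance
#' variability, lesion sampling, multiplicative measurement noise with the
#' plasma denominator shared within a patient), how much the seed-averaged
#' sample medians drift above the noise-free medians -- the sample median
#' of noisy right-skewed data is biased upward -- and refits against
#' drift-corrected targets.  The four medians slightly over-determine the
#' model family, leaving residuals of about 6\% on the cycle-1 points;
#' these are reported, not hidden.
#'
#' @param k1 plasma-to-tissue transfer of the median lesion, mL g^-1 h^-1.
#' @param k2 efflux, 1/h.
#' @param ki_nonspec tumor non-saturable floor, uL g^-1 h^-1.
#' @param sigma_w log-scale SD of the lesion-level specific-Ki distribution.
#' @param gamma exponent coupling perfusion (`k1`, `vb`) to the lesion
#'   kinetic scale.
#' @param noise_cv measurement-noise level of the study conditions the
#'   correction accounts for.
#' @param n_sim Monte-Carlo cohort replicates per correction iteration.
#' @return list with the median-lesion [TissueKineticParams-class]
#'   (`params`), the tumor [OccupancyModel-class] (`occupancy`),
#'   `ki_spec_median`, `sigma_w`, `gamma`, the expected seed-averaged
#'   simulated medians (`predicted`), the noise-free model medians
#'   (`predicted_noise_free`), the targets themselves (`targets`) and the
#'   maximal relative residual of `predicted` (`max_rel_residual`).
#' @examples
#' calibrateTumorModel()$predicted
#' @export
calibrateTumorModel <- function(k1 = 0.06, k2 = 0.2, ki_nonspec = 0.1,
                                sigma_w = 1.0, gamma = 0.3, noise_cv = 0.1,
                                n_sim = 600) {
  key <- paste("tumor_cal", k1, k2, ki_nonspec, sigma_w, gamma, noise_cv,
               n_sim, sep = "_")
  .memo(key, function() {
    ref <- referenceCohortSummaries()
    targets <- ref$tumor_t2p_median
    inputs <- list(plasmaModelForDose(4), plasmaModelForDose(44),
                   plasmaModelForDose(604))
    spec <- list(c(1, 90, 4), c(1, 138, 4), c(2, 138, 44), c(3, 138, 604))
    predict4 <- function(vb, ks, d50) {
      occm <- OccupancyModel(d50 = d50, hill = 2)
      vapply(spec, function(s) {
        occ <- receptorOccupancy(s[3], occm)
        ki <- ki_nonspec + ks * (1 - occ)
        pars <- TissueKineticParams(vb = vb, k1 = k1, k2 = k2,
                                    k3_max = .k3ForKiSpec(ks, k1, k2),
                                    ki_nonspec = ki_nonspec)
        tac <- simulateTissueCurve(pars, 1 - (ki - ki_nonspec) /
                                     (effectiveKi(pars, 0) - ki_nonspec),
                                   inputs[[s[1]]], s[2])
        tacConc(tac) / tacConc(simulatePlasmaCurve(inputs[[s[1]]], s[2]))
      }, 0)
    }
    sse <- function(p) {
      r <- predict4(exp(p[1]), exp(p[2]), exp(p[3]))
      if (any(!is.finite(r)) || any(r <= 0)) return(1e6)
      sum((log(r) - log(targets))^2)
    }
    fitLS <- function(tg) {
      sse <- function(p) {
        r <- predict4(exp(p[1]), exp(p[2]), exp(p[3]))
        if (any(!is.finite(r)) || any(r <= 0)) return(1e6)
        sum((log(r) - log(tg))^2)
      }
      opt <- stats::optim(log(c(0.2, 5, 15)), sse, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-14))
      exp(opt$par)
    }
    ## stage 1: analytic fit of the noise-free median lesion
    th <- fitLS(targets)
    ## stage 2: correct for the upward drift of noisy sample medians
    ## (iterative proportional adjustment under the generative law)
    if (noise_cv > 0) {
      for (it in 1:2) {
        sim <- .withSeed(745001 + it,
                         .mcCohortMedians(th[1], th[2], th[3], k1, k2,
                                          ki_nonspec, sigma_w, gamma,
                                          noise_cv, n_sim))
        uplift <- sim / predict4(th[1], th[2], th[3])
        th <- fitLS(targets / uplift)
      }
      pred <- .withSeed(745000,
                        .mcCohortMedians(th[1], th[2], th[3], k1, k2,
                                         ki_nonspec, sigma_w, gamma,
                                         noise_cv, 2 * n_sim))
    } else {
      pred <- predict4(th[1], th[2], th[3])
    }
    vb <- th[1]; ks <- th[2]; d50 <- th[3]
    pred_nf <- predict4(vb, ks, d50)
    names(pred) <- names(pred_nf) <- names(targets)
    list(params = TissueKineticParams(vb = vb, k1 = k1, k2 = k2,
                                      k3_max = .k3ForKiSpec(ks, k1, k2),
                                      ki_nonspec = ki_nonspec),
         occupancy = OccupancyModel(d50 = d50, hill = 2),
         ki_spec_median = ks, sigma_w = sigma_w, gamma = gamma,
         predicted = pred, predicted_noise_free = pred_nf,
         targets = targets,
         max_rel_residual = max(abs(pred / targets - 1)))
  })
}

## Monte-Carlo expectation of the seed-averaged tumor-to-plasma sample
## medians under the full generative law: patient-level clearance
## variability, 3/3 arm split, 2-5 lesions per patient with log-normal
## kinetic scale, multiplicative measurement noise with the plasma
## denominator shared within a patient.  Closed-form curves, vectorized
## over lesions.
.mcCohortMedians <- function(vb, ks, d50, k1, k2, ki_nonspec, sigma_w,
                             gamma, noise_cv, n_sim) {
  arms <- list(`4` = plasmaModelForDose(4), `44` = plasmaModelForDose(44),
               `604` = plasmaModelForDose(604))
  occ <- vapply(c(4, 44, 604), function(d) d^2 / (d^2 + d50^2), 0)
  names(occ) <- c("4", "44", "604")
  ratioVec <- function(w, cl, dose, t) {
    pk <- arms[[dose]]
    A <- c(pk@amp_fast, pk@amp_slow)
    l <- c(pk@lambda_fast, pk@lambda_slow * pk@clearance_scale * cl)
    cp <- sum(A * exp(-l * t))
    vbw <- vb * w^gamma
    k1w <- k1 * w^gamma
    ki_eff <- ki_nonspec + ks * w * (1 - occ[[dose]])
    q <- pmin(ki_eff / (1000 * k1w), 0.95)
    k3 <- k2 * q / (1 - q)
    b <- k2 + k3
    ct <- vbw * cp
    for (i in 1:2) {
      near <- abs(b - l[i]) < 1e-9
      ed <- ifelse(near, t * exp(-l[i] * t),
                   (exp(-l[i] * t) - exp(-b * t)) / (b - l[i]))
      edi <- ifelse(near,
                    (1 - (1 + l[i] * t) * exp(-l[i] * t)) / l[i]^2,
                    ((1 - exp(-l[i] * t)) / l[i] - (1 - exp(-b * t)) / b) /
                      (b - l[i]))
      ct <- ct + k1w * A[i] * ed + k1w * k3 * A[i] * edi
    }
    ct / cp
  }
  noisyMedian <- function(r, pat) {
    eps <- pmax(stats::rnorm(length(r), 0, noise_cv), -0.99)
    del <- pmax(stats::rnorm(max(pat), 0, noise_cv), -0.99)
    stats::median(r * (1 + eps) / (1 + del[pat]))
  }
  acc <- matrix(0, n_sim, 4)
  for (s in seq_len(n_sim)) {
    cl <- exp(stats::rnorm(6, 0, 0.15))
    n_les <- sample(2:5, 6, replace = TRUE)
    pat <- rep(1:6, n_les)
    w <- exp(sigma_w * stats::qnorm(stats::runif(sum(n_les))))
    r4_90 <- vapply(seq_along(w), function(j)
      ratioVec(w[j], cl[pat[j]], "4", 90), 0)
    r4_138 <- vapply(seq_along(w), function(j)
      ratioVec(w[j], cl[pat[j]], "4", 138), 0)
    in44 <- pat >= 4   # second half of the cohort receives the 44-mg arm
    r44 <- vapply(which(in44), function(j)
      ratioVec(w[j], cl[pat[j]], "44", 138), 0)
    r604 <- vapply(which(!in44), function(j)
      ratioVec(w[j], cl[pat[j]], "604", 138), 0)
    acc[s, ] <- c(noisyMedian(r4_90, pat), noisyMedian(r4_138, pat),
                  noisyMedian(r44, pat[in44] - 3),
                  noisyMedian(r604, pat[!in44]))
  }
  colMeans(acc)
}

## k3 such that 1000 k1 k3 / (k2 + k3) equals the requested specific Ki
.k3ForKiSpec <- function(ki_spec, k1, k2) {
  q <- ki_spec / (1000 * k1)
  if (q >= 1) stop("requested specific Ki exceeds 1000*k1")
  k2 * q / (1 - q)
}
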