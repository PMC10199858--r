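test_that("input-function fitting recovers noiseless parameters", {
  truth <- plasmaModelForDose(4)
  cp <- simulatePlasmaCurve(truth, c(1, 2, 24, 48, 90, 138))
  fit <- fitInputFunction(cp)
  expect_equal(fit@params$A1, truth@amp_fast, tolerance = 1e-6)
  expect_equal(fit@params$A2, truth@amp_slow, tolerance = 1e-6)
  expect_equal(fit@params$l2, truth@lambda_slow * truth@clearance_scale,
               tolerance = 1e-6)
  expect_lt(fit@fit_residual, 1e-7)
})

test_that("sparse-sample fit recovers the terminal slope", {
  truth <- plasmaModelForDose(4)
  cp <- simulatePlasmaCurve(truth, c(1, 91, 139))
  fit <- fitInputFunction(cp)
  ## oracle: two-point slope on the last two samples (fast phase dead)
  y <- tacConc(cp)
  lam_oracle <- log(y[2] / y[3]) / 48
  expect_equal(fit@params$l2, lam_oracle, tolerance = 0.01)
  expect_equal(fit@params$l2, truth@lambda_slow * truth@clearance_scale,
               tolerance = 0.05)
  expect_error(fitInputFunction(
    TimeActivityCurve("plasma", 1, 20, region_type = "plasma")), "2 plasma")
})

test_that("the log-linear interpolant reproduces samples at the knots", {
  cp <- TimeActivityCurve("plasma", c(1, 91, 139), c(24, 6.1, 3.3),
                          region_type = "plasma")
  fit <- fitInputFunction(cp, model = "loglinear_interp")
  expect_equal(inputConc(fit, c(1, 91, 139)), c(24, 6.1, 3.3))
  ## its integral matches numeric quadrature
  num <- integrate(function(t) inputConc(fit, t), 0, 120,
                   subdivisions = 2000, rel.tol = 1e-10)$value
  expect_equal(inputIntegral(fit, 120), num, tolerance = 1e-8)
})

test_that("Patlak transformation has its analytic identities", {
  ## constant input: x(t) = t exactly
  flat <- fitInputFunction(
    TimeActivityCurve("plasma", c(1, 200), c(10, 10), region_type = "plasma"),
    model = "loglinear_interp")
  tis <- TimeActivityCurve("r", c(10, 50, 150), c(1, 2, 3))
  pts <- patlakTransform(tis, flat)
  expect_equal(pts$x, c(10, 50, 150), tolerance = 1e-12)

  ## single-exponential input: x(t) = (exp(l t) - 1) / l, and quadrature
  lam <- 0.01
  single <- new("InputFunctionFit", model = "biexponential",
                params = list(A1 = 0, l1 = 1, A2 = 10, l2 = lam),
                fit_residual = 0)
  pts <- patlakTransform(TimeActivityCurve("r", c(30, 90), c(1, 1)), single)
  expect_equal(pts$x, (exp(lam * c(30, 90)) - 1) / lam, tolerance = 1e-10)
  quad <- integrate(function(t) inputConc(single, t), 0, 90,
                    rel.tol = 1e-12)$value
  expect_equal(pts$x[2], quad / inputConc(single, 90), tolerance = 1e-8)

  ## pure blood-volume tissue: y == vb everywhere
  input <- plasmaModelForDose(4)
  vb_only <- simulateTissueCurve(TissueKineticParams(vb = 0.21, k1 = 0),
                                 0, input, c(2, 90, 138))
  pts <- patlakTransform(vb_only, input)
  expect_equal(pts$y, rep(0.21, 3), tolerance = 1e-12)

  expect_error(patlakTransform(
    TimeActivityCurve("r", 300, 1),
    fitInputFunction(TimeActivityCurve("plasma", c(1, 138), c(20, 3),
                                       region_type = "plasma"),
                     model = "loglinear_interp")), "domain")
})

test_that("Patlak OLS matches exact lines and a grid-search oracle", {
  x <- c(50, 120, 300, 410)
  pts <- data.frame(t = c(30, 60, 100, 138), x = x, y = 0.3 + 0.002 * x)
  fit <- patlakFit(pts, window = c(0, Inf))
  expect_equal(kiValue(fit), 2.0, tolerance = 1e-12)
  expect_equal(vIntercept(fit), 0.3, tolerance = 1e-12)
  expect_equal(rSquared(fit), 1)

  ## noisy points vs brute-force SSE grid minimization over (a, b)
  set.seed(31)
  pts$y <- 0.3 + 0.002 * x + rnorm(4, 0, 0.05)
  fit <- patlakFit(pts, window = c(0, Inf))
  a <- 0.3; b <- 0.002; ra <- 0.3; rb <- 0.003
  for (it in 1:12) {
    agrid <- seq(a - ra, a + ra, length.out = 41)
    bgrid <- seq(b - rb, b + rb, length.out = 41)
    sse <- outer(agrid, bgrid, function(A, B)
      vapply(seq_along(A), function(i)
        sum((pts$y - A[i] - B[i] * pts$x)^2), 0))
    ix <- which(sse == min(sse), arr.ind = TRUE)[1, ]
    a <- agrid[ix[1]]; b <- bgrid[ix[2]]
    ra <- ra / 8; rb <- rb / 8
  }
  expect_equal(kiValue(fit) / 1000, b, tolerance = 1e-6)
  expect_equal(vIntercept(fit), a, tolerance = 1e-6)

  ## degenerate abscissa spread
  expect_error(patlakFit(data.frame(t = c(90, 138), x = c(100, 100),
                                    y = c(1, 2))), "degenerate")
  ## negative slopes flagged, not clamped
  neg <- patlakFit(data.frame(t = c(90, 138), x = c(100, 200), y = c(2, 1)))
  expect_lt(kiValue(neg), 0)
  expect_true("negative_slope" %in% neg@flags)
})

test_that("noise-free spleen simulation recovers the published Ki", {
  occm <- calibrateOccupancy()$model
  sp <- spleenParams()
  input <- plasmaModelForDose(4)
  tac <- simulateTissueCurve(sp, receptorOccupancy(4, occm), input,
                             c(2, 90, 138))
  fit <- patlakFit(patlakTransform(tac, input))
  expect_equal(kiValue(fit), 30.06, tolerance = 0.02)
  expect_equal(fit@n_points, 2L)
  ## intercept at least the fractional blood volume
  expect_gte(vIntercept(fit), sp@vb)
  ## Ki invariant under common rescaling of tissue and plasma
  both <- patlakTransform(tac, input)
  both$y <- both$y  # ratio already scale-free; rescale via curves instead
  scaled_tac <- TimeActivityCurve("spleen", tacTimes(tac), tacConc(tac) * 3)
  scaled_in <- PlasmaPKParams(input@amp_fast * 3, input@amp_slow * 3,
                              input@lambda_fast, input@lambda_slow,
                              input@clearance_scale)
  fit2 <- patlakFit(patlakTransform(scaled_tac, scaled_in))
  expect_equal(kiValue(fit2), kiValue(fit), tolerance = 1e-10)
})

test_that("Patlak slope converges to 1000*k1*k3/(k2+k3) after equilibration", {
  input <- plasmaModelForDose(4)
  for (pars in list(TissueKineticParams(0.1, 0.05, 0.3, 0.05, 0),
                    TissueKineticParams(0.3, 0.1, 0.15, 0.1, 0.5),
                    spleenParams())) {
    tac <- simulateTissueCurve(pars, 0, input, c(2, 90, 138))
    fit <- patlakFit(patlakTransform(tac, input))
    expect_equal(kiValue(fit), effectiveKi(pars, 0), tolerance = 0.02)
    expect_gte(vIntercept(fit), pars@vb)
  }
})
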