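test_that("decay correction follows the half-life law", {
  expect_equal(decayCorrect(100, 0), 100)
  expect_equal(decayCorrect(100, 78.41, 78.41), 200)
  expect_equal(decayUncorrect(decayCorrect(123.4, 90), 90), 123.4,
               tolerance = 1e-12)
  expect_error(decayCorrect(100, -5), "elapsed")
  expect_error(decayCorrect(100, 5, 0), "half_life")
})

test_that("percent injected activity is the stated arithmetic identity", {
  inj <- InjectionRecord(activity_mbq = 37)
  expect_equal(percentInjectedActivity(37, inj), 0.1)
  expect_equal(percentInjectedActivity(0, inj), 0)
  expect_equal(percentInjectedActivity(74, inj),
               2 * percentInjectedActivity(37, inj))
  expect_error(percentInjectedActivity(10, InjectionRecord(activity_mbq = 0)))
})

test_that("SUV uses the injected activity per body weight", {
  inj <- InjectionRecord(37, 4, 74)
  expect_equal(suv(0, inj), 0)
  expect_equal(suv(500, inj), 500 / (37e6 / 74000))  # = 1.0 by hand
  expect_equal(suv(500, inj), 1.0)
  expect_equal(suv(37e6 / 74000, inj), 1)
  expect_error(suv(10, InjectionRecord(37, 4, 0)))
})

test_that("tissue-to-plasma ratios pair by nearest time and rescale-invariance", {
  tis <- TimeActivityCurve("spleen", c(90, 138), c(12, 9))
  pl <- TimeActivityCurve("plasma", c(1, 91, 139), c(20, 6, 3),
                          region_type = "plasma")
  r <- tissueToPlasmaRatio(tis, pl)
  expect_equal(r$ratio, c(12 / 6, 9 / 3))
  expect_equal(r$plasma_time_h, c(91, 139))
  ## tissue == plasma -> ratio 1
  same <- tissueToPlasmaRatio(pl, pl)
  expect_equal(same$ratio, c(1, 1, 1))
  ## common rescaling leaves the ratio unchanged
  sc <- tissueToPlasmaRatio(
    TimeActivityCurve("spleen", c(90, 138), c(12, 9) * 7.3),
    TimeActivityCurve("plasma", c(1, 91, 139), c(20, 6, 3) * 7.3,
                      region_type = "plasma"))
  expect_equal(sc$ratio, r$ratio)
  ## no plasma sample within tolerance -> explicit error
  expect_error(tissueToPlasmaRatio(
    TimeActivityCurve("spleen", 50, 5), pl), "within")
  expect_error(tissueToPlasmaRatio(
    TimeActivityCurve("spleen", 91, 5),
    TimeActivityCurve("plasma", 91, 0, region_type = "plasma")), "positive")
})

test_that("pipeline ratios equal the forward model on noise-free data", {
  ## cross-module identity: Bq/mL -> decay correction -> %IA/L -> ratio
  ## reproduces C_t(t)/C_p(t) of the generating kinetic model
  coh <- noiseFreeCohort()
  up <- uptakeTable(coh)
  les <- lesionTruth(coh)[1, ]
  pp <- cohortTruth(coh)$plasma_params
  pp1 <- plasmaParamsFromTruth(pp[pp$patient_id == les$patient_id &
                                    pp$cycle == 1, ])
  occ <- receptorOccupancy(4, cohortTruth(coh)$occupancy$tumor)
  ct <- tacConc(simulateTissueCurve(lesionParamsFromTruth(les), occ, pp1, 138))
  cp <- tacConc(simulatePlasmaCurve(pp1, 138))
  got <- up$value[up$region_id == les$lesion_id & up$cycle == 1 &
                    up$time_h == 138 & up$measure_kind == "tissue_to_plasma"]
  expect_equal(got, ct / cp, tolerance = 1e-10)
})

test_that("tumor ratios increase from 90 to 138 h in the tracer-only cycle", {
  up <- uptakeTable(noiseFreeCohort())
  t2p <- up[up$measure_kind == "tissue_to_plasma" & up$region_type == "tumor" &
              up$cycle == 1, ]
  wide <- merge(t2p[t2p$time_h == 90, c("region_id", "value")],
                t2p[t2p$time_h == 138, c("region_id", "value")],
                by = "region_id", suffixes = c("_90", "_138"))
  expect_true(all(wide$value_138 > wide$value_90))
})

test_that("quantification commutes with measurement noise in expectation", {
  inj <- InjectionRecord(37, 4, 75)
  one <- TimeActivityCurve("r", 90, 1000)
  draws <- vapply(seq_len(1e4),
                  function(i) tacConc(addNoise(one, 0.1, seed = i)), 0)
  expect_equal(mean(percentInjectedActivity(draws, inj)),
               percentInjectedActivity(1000, inj), tolerance = 0.01)
  expect_equal(mean(suv(draws, inj)), suv(1000, inj), tolerance = 0.01)
  expect_equal(mean(draws / 250), 1000 / 250, tolerance = 0.01)
})
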