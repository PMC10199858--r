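test_that("default cohort reproduces the study design", {
  coh <- generateCohort(CohortConfig(seed = 7))
  cfg <- cohortConfig(coh)
  expect_equal(cfg@n_patients, 6L)
  expect_equal(sort(as.integer(table(cfg@arm_assignment))), c(3L, 3L))
  les <- lesionTruth(coh)
  per_pat <- table(les$patient_id)
  expect_true(all(per_pat >= 2 & per_pat <= 5))
  expect_true(nrow(les) >= 12 && nrow(les) <= 30)
  ## every TAC row has a matching injection record
  key_tac <- unique(paste(coh@tac$patient_id, coh@tac$cycle))
  key_inj <- paste(coh@injections$patient_id, coh@injections$cycle)
  expect_true(all(key_tac %in% key_inj))
})

test_that("cohorts are a pure function of configuration and seed", {
  c1 <- generateCohort(CohortConfig(seed = 42))
  c2 <- generateCohort(CohortConfig(seed = 42))
  expect_identical(c1@plasma, c2@plasma)
  expect_identical(c1@tac, c2@tac)
  expect_identical(c1@lesions, c2@lesions)
  c3 <- generateCohort(CohortConfig(seed = 43))
  expect_false(identical(c1@tac, c3@tac))
  ## generation does not disturb the caller's RNG stream
  set.seed(5); a <- runif(3)
  set.seed(5); invisible(generateCohort(CohortConfig(seed = 42)))
  expect_identical(runif(3), a)
})

test_that("noise-free observations equal the forward model exactly", {
  coh <- noiseFreeCohort()
  les <- lesionTruth(coh)[1, ]
  pp <- cohortTruth(coh)$plasma_params
  pp1 <- pp[pp$patient_id == les$patient_id & pp$cycle == 1, ]
  occ <- receptorOccupancy(4, cohortTruth(coh)$occupancy$tumor)
  tac_exp <- simulateTissueCurve(lesionParamsFromTruth(les), occ,
                                 plasmaParamsFromTruth(pp1), c(2, 90, 138))
  obs <- coh@tac[coh@tac$region_id == les$lesion_id & coh@tac$cycle == 1, ]
  ## convert the simulated %IA/L back to measured Bq/mL
  exp_bq <- decayUncorrect(tacConc(tac_exp) * 37e6 / 1e5, c(2, 90, 138))
  expect_equal(obs$conc_bq_per_ml, exp_bq, tolerance = 1e-12)
})

test_that("impossible configurations are rejected", {
  expect_error(CohortConfig(scan_times_c1 = c(0, 90, 138)), "positive")
  expect_error(CohortConfig(scan_times_c1 = c(90, 2, 138)), "increasing")
  expect_error(CohortConfig(arm_assignment = c(`1` = 10, `2` = 604, `3` = 604,
                                               `6` = 44, `9` = 44, `10` = 44)),
               "44 or 604")
  expect_error(CohortConfig(lesions_max = 9L), "lesion count")
  expect_error(CohortConfig(noise_cv = -0.1), "noise_cv")
})

test_that("multiplicative noise has the stated law", {
  tac <- TimeActivityCurve("r", c(1, 2), c(10, 20))
  expect_identical(addNoise(tac, 0), tac)
  expect_error(addNoise(tac, -0.1), "cv")
  ## Monte-Carlo: sample SD/mean of one noisy point at cv = 0.1
  one <- TimeActivityCurve("r", 1, 100)
  draws <- vapply(seq_len(1e4),
                  function(i) tacConc(addNoise(one, 0.1, seed = i)), 0)
  expect_gt(sd(draws) / mean(draws), 0.095)
  expect_lt(sd(draws) / mean(draws), 0.105)
  ## truncation keeps values strictly positive even at cv = 0.5
  set.seed(9)
  vals <- ImmunoPatlak:::.noisyValues(rep(1, 1e5), 0.5)
  expect_true(all(vals > 0))
})

test_that("a cohort round-trips through its directory representation", {
  coh <- generateCohort(CohortConfig(seed = 12))
  d <- withr::local_tempdir()
  writeCohort(coh, d)
  expect_true(all(file.exists(file.path(d, c("cohort.json", "plasma.csv",
                                             "tac.csv", "injections.csv",
                                             "lesions.csv")))))
  back <- readCohort(d)
  expect_equal(back@plasma, coh@plasma, tolerance = 1e-12)
  expect_equal(back@tac, coh@tac, tolerance = 1e-12)
  expect_equal(back@config@arm_assignment, coh@config@arm_assignment)
  ## writing the same cohort twice is byte-identical
  d2 <- withr::local_tempdir()
  writeCohort(coh, d2)
  for (f in c("plasma.csv", "tac.csv", "injections.csv", "lesions.csv",
              "cohort.json"))
    expect_identical(unname(tools::md5sum(file.path(d, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})
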