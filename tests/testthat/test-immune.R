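test_that("signature scores have the stated invariances", {
  const <- matrix(5, 4, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  expect_warning(sc <- signatureScore(const, c("g1", "g2")), "zero-variance")
  expect_equal(unname(sc), rep(0, 4))

  ## one gene, two samples: symmetric z-scores summing to zero
  m <- matrix(c(0, 2), 2, 1, dimnames = list(NULL, "g1"))
  sc <- signatureScore(m, "g1")
  expect_equal(unname(sc), c(-1, 1) / sqrt(2))
  expect_equal(sum(sc), 0)

  set.seed(4)
  expr <- matrix(rnorm(60), 6, 10,
                 dimnames = list(NULL, sprintf("g%d", 1:10)))
  set_a <- c("g1", "g4", "g7")
  base <- signatureScore(expr, set_a)
  ## gene order within the set is irrelevant
  expect_equal(signatureScore(expr, rev(set_a)), base)
  ## adding a constant to a whole gene row (column) changes nothing
  shifted <- expr; shifted[, "g4"] <- shifted[, "g4"] + 100
  expect_equal(signatureScore(shifted, set_a), base)
  ## column reordering of the matrix changes nothing
  expect_equal(signatureScore(expr[, sample(10)], set_a), base)

  expect_error(signatureScore(expr, character(0)), "non-empty")
  expect_error(signatureScore(expr, "nope"), "absent")
  expect_error(signatureScore(expr[1, , drop = FALSE], "g1"), "2 samples")
})

test_that("signature genes driven by infiltration yield high rank correlation", {
  rhos <- vapply(1:100, function(s) {
    infil <- stats::runif(20)
    sim <- simulateExpression(infil, noise_sd = 0.5, seed = s)
    sc <- signatureScore(sim$expr, sim$gene_set)
    cor(rank(sc), rank(infil))
  }, 0)
  expect_gt(median(rhos), 0.8)
})

test_that("Spearman correlation and its exact permutation p-value", {
  expect_equal(correlateUptakeInfiltration(1:5, c(2, 4, 6, 7, 9))$rho, 1)
  expect_equal(correlateUptakeInfiltration(1:5, -(1:5))$rho, -1)
  expect_error(correlateUptakeInfiltration(1:5, rep(1, 5)), "constant")
  expect_error(correlateUptakeInfiltration(1:2, 2:1), "at least 3")

  ## n = 5 fixture: p equals enumeration over all 120 permutations,
  ## generated here by an independent recursive routine
  x <- c(0.8, 1.4, 3.0, 3.2, 3.6); y <- c(1, 5, 10, 4, 30)
  res <- correlateUptakeInfiltration(x, y)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  rhos <- vapply(perms(rank(y)), function(p) cor(rank(x), p), 0)
  expect_equal(res$p, mean(abs(rhos) >= abs(res$rho) - 1e-12))
  expect_equal(res$method, "exact_permutation")
  ## larger n switches to the t approximation
  expect_equal(correlateUptakeInfiltration(1:9, c(2, 1, 4, 3, 6, 5, 8, 7, 9))$method,
               "t_approximation")
})

test_that("phenotype classification applies the >= 3.0 convention", {
  ratios <- referenceCohortSummaries()$patient_mean_t2p_138h
  ph <- classifyPhenotype(ratios)
  expect_equal(sum(ph$label == "infiltrated"), 4)
  expect_equal(sum(ph$label == "desert"), 2)
  expect_equal(ph$label[ph$patient_id %in% c("6", "9")], rep("desert", 2))
  ## boundary: exactly 3.0 counts as infiltrated
  expect_equal(classifyPhenotype(c(a = 3.0))$label, "infiltrated")
  ## empty threshold falls back to the 3.0 default
  expect_equal(classifyPhenotype(c(a = 3.0), threshold = NULL)$threshold, 3)
})

test_that("desert-labelled patients have lower true infiltration", {
  hits <- 0; informative <- 0
  for (s in 1:30) {
    coh <- generateCohort(CohortConfig(seed = 1000 + s))
    im <- immuneSummary(coh)
    if (length(unique(im$phenotype)) < 2) next
    infil <- stats::aggregate(infiltration ~ patient_id, lesionTruth(coh),
                              stats::median)
    by_lab <- split(stats::setNames(infil$infiltration, infil$patient_id)[im$patient_id],
                    im$phenotype)
    informative <- informative + 1
    if (median(by_lab$desert) < median(by_lab$infiltrated)) hits <- hits + 1
  }
  expect_gt(informative, 10)
  expect_gte(hits / informative, 0.95)
})
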