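test_that("parametric accuracy formulas reproduce the design values", {
  expect_equal(round(parametricAccuracyAdditive(1000, 100, 0.93, 0.20,
                                                0.30), 2), 0.68)
  expect_equal(round(parametricAccuracyAdditive(1000, 100, 0.93, 0.35,
                                                0.50), 2), 0.73)
  expect_equal(round(parametricAccuracyDominance(1000, 100, 0.93, 0.10,
                                                 0.30), 2), 0.48)
  expect_equal(round(parametricAccuracyDominance(1000, 100, 0.93, 0.17,
                                                 0.50), 2), 0.51)
  expect_equal(parametricAccuracyAdditive(1000, 100, 0.93, 0, 0.30), 0)
  expect_error(parametricAccuracyAdditive(1000, 0, 0.93, 0.2, 0.3),
               "n_qtl")
})

test_that("parametric accuracies are monotone in their drivers", {
  base <- parametricAccuracyAdditive(1000, 100, 0.93, 0.20, 0.30)
  expect_gt(parametricAccuracyAdditive(2000, 100, 0.93, 0.20, 0.30), base)
  expect_gt(parametricAccuracyAdditive(1000, 100, 0.93, 0.25, 0.35), base)
  expect_lt(parametricAccuracyAdditive(1000, 200, 0.93, 0.20, 0.30), base)
})

test_that("genotypic accuracy combines components in quadrature", {
  expect_equal(parametricAccuracyGenotypic(0, 0.5), 0.5)
  expect_equal(parametricAccuracyGenotypic(0.6, 0.8), 1.0)
  ra <- parametricAccuracyAdditive(1000, 100, 0.93, 0.20, 0.30)
  rd <- parametricAccuracyDominance(1000, 100, 0.93, 0.10, 0.30)
  rg <- parametricAccuracyGenotypic(ra, rd)
  expect_equal(rg, sqrt(ra^2 + rd^2))
  expect_gte(rg, max(ra, rd))
  expect_error(parametricAccuracyGenotypic(0.9, 0.9), "exceeds")
})

test_that("empirical accuracy and bias behave on canonical inputs", {
  x <- rnorm(50)
  expect_equal(unname(empiricalAccuracyBias(x, x)), c(1, 1))
  half <- empiricalAccuracyBias(0.5 * x, x)
  expect_equal(unname(half), c(1, 2))
  set.seed(80)
  noise <- empiricalAccuracyBias(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(noise["cor"]), 3 / sqrt(1e4))
  expect_error(empiricalAccuracyBias(rep(1, 10), rnorm(10)),
               "zero-variance")
  expect_error(empiricalAccuracyBias(rnorm(5), rnorm(6)), "equal length")
})

test_that("criteria scoring reproduces the printed scenario-1 ranking", {
  report <- scenario1PrintedReport()
  scores <- scoreBestCriteria(report, scenario1Parametric())
  expect_equal(unname(scores["BAYESA*B*(-2,8)"]), 7L)
  expect_equal(unname(scores["IBLASSO(4,-2)"]), 1L)
  expect_equal(unname(scores["RR-HET(-2,-2)"]), 1L)
  expect_equal(unname(scores["BAYESA*B*(4,6)"]), 6L)
  expect_equal(unname(scores["BAYESA*B*(-2,6)"]), 5L)
  expect_equal(unname(scores["G-BLUP"]), 5L)
  expect_equal(unname(scores["IBLASSO(4,2)"]), 4L)
  expect_equal(unname(scores["Pedigree-BLUP"]), 2L)
  ## identical methods share every criterion
  same <- report[rep(1, 3), ]
  same$method <- letters[1:3]
  expect_equal(unname(scoreBestCriteria(same, scenario1Parametric())),
               rep(7L, 3))
})

test_that("the validation protocol estimates and transfers marker effects", {
  map <- smallMap()
  reps <- simulateStudy(map = map, n_replicates = 3, n_families = 4,
                        family_size = 20, pop_size = 300, seed = 900)
  report <- runValidation(reps, methods = c("G-BLUP", "Pedigree-BLUP"),
                          n_iter = 1000, burn_in = 200, thin = 2,
                          seed = 3)
  expect_equal(nrow(report), 2)
  expect_true(all(c("h2a", "h2d", "cor_a", "by_a", "cor_d", "by_d",
                    "vd_va", "cor_a_sd") %in% names(report)))
  expect_true(all(abs(report$cor_a) <= 1))
  ## determinism: same seed, same report
  report2 <- runValidation(reps, methods = c("G-BLUP", "Pedigree-BLUP"),
                           n_iter = 1000, burn_in = 200, thin = 2,
                           seed = 3)
  keep <- setdiff(names(report), "seconds")  # wall time is informational
  expect_equal(report[keep], report2[keep])
  ## genomic prediction should carry real signal across replicates
  expect_gt(report$cor_a[report$method == "G-BLUP"], 0.2)
  expect_error(runValidation(reps[1], methods = "G-BLUP"),
               "at least 2")
})

test_that("self-validation with a noiseless trait approaches perfect accuracy", {
  rep <- smallReplicate()
  cd <- rep$coding
  ## purely additive noiseless response: essentially exact recovery
  ua <- rep$truth$u_a
  fit_a <- fitREML(ua, list(a = buildGa(cd), d = buildGd(cd)))
  mr_a <- markerRidge(ua, cd@W, cd@S, fit_a$sigma2[["a"]] / cd@sum2pq,
                      fit_a$sigma2[["d"]] / cd@sum2pq_sq,
                      max(fit_a$sigma2[["e"]], 1e-8 * var(ua)))
  expect_gt(cor(mr_a$ua, ua), 0.99)
  ## noiseless genotypic response: additive accuracy stays near the
  ## ceiling despite additive-dominance crosstalk
  g <- rep$truth$g
  fit_g <- fitREML(g, list(a = buildGa(cd), d = buildGd(cd)))
  mr_g <- markerRidge(g, cd@W, cd@S, fit_g$sigma2[["a"]] / cd@sum2pq,
                      fit_g$sigma2[["d"]] / cd@sum2pq_sq,
                      max(fit_g$sigma2[["e"]], 1e-8 * var(g)))
  expect_gt(cor(mr_g$ua, ua), 0.9)
})
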