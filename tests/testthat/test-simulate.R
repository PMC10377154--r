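test_that("simulation specs validate their fields", {
  expect_error(SimulationSpec("periodic", model = "independence"),
               "independence")
  expect_error(SimulationSpec("gp", nGroups = 1), "nGroups")
  expect_error(SimulationSpec("gp", pointsPerGroup = 1), "pointsPerGroup")
  expect_error(simulateGP(SimulationSpec("periodic", model = "shift")),
               "generator")
})

test_that("generators are reproducible under a fixed seed", {
  for (gen in c("gp", "periodic", "polynomial")) {
    sim <- switch(gen, gp = simulateGP, periodic = simulatePeriodic,
                  polynomial = simulatePolynomial)
    spec <- SimulationSpec(gen, model = "shift", nGenes = 3,
                           pointsPerGroup = 8, seed = 42)
    a <- sim(spec); b <- sim(spec)
    expect_identical(SummarizedExperiment::assay(a, "expr"),
                     SummarizedExperiment::assay(b, "expr"))
    expect_identical(trueShifts(a), trueShifts(b))
  }
})

test_that("periodic generator follows the shifted sine exactly", {
  spec <- SimulationSpec("periodic", model = "shift", nGenes = 2,
                         pointsPerGroup = 12, noiseSD = 0, seed = 43)
  se <- simulatePeriodic(spec)
  tt <- SummarizedExperiment::assay(se, "time")
  y <- SummarizedExperiment::assay(se, "expr")
  grp <- SummarizedExperiment::colData(se)$group
  dt <- trueShifts(se)
  for (k in 1:2) {
    shift <- ifelse(grp == "g2", dt[k, "g2"], 0)
    expect_equal(unname(y[k, ]),
                 unname(sin(2 * pi * (tt[k, ] - shift) / 10)))
  }
  expect_true(all(dt[, "g1"] == 0))
  expect_true(all(dt[, "g2"] == 2))     # fixed two-group offset
  # the sine peaks at quarter period
  expect_equal(sin(2 * pi * 2.5 / 10), 1)
})

test_that("polynomial generator follows the shifted quadratic exactly", {
  spec <- SimulationSpec("polynomial", model = "shift", nGenes = 1,
                         pointsPerGroup = 10, noiseSD = 0, seed = 44)
  se <- simulatePolynomial(spec)
  tt <- SummarizedExperiment::assay(se, "time")[1, ]
  y <- SummarizedExperiment::assay(se, "expr")[1, ]
  grp <- SummarizedExperiment::colData(se)$group
  u <- tt - ifelse(grp == "g2", 2, 0)
  expect_equal(unname(y), unname(1.5 * (u - 10) + (u - 10)^2))
  # direct evaluation with the default coefficients
  f <- function(x) 1.5 * (x - 10) + (x - 10)^2
  expect_equal(f(10), 0)
  expect_equal(f(12), 7)
})

test_that("a noiseless shared draw is identical across duplicated grids", {
  spec <- SimulationSpec("gp", model = "no_shift", nGenes = 1,
                         pointsPerGroup = 10, seed = 45)
  tt <- sort(runif(10, 5, 15))
  set.seed(45)
  f <- tempshift:::.latentDraw(spec, list(tt, tt), c(0, 0))
  expect_equal(f[1:10], f[11:20], tolerance = 1e-2)
})

test_that("GP draws reproduce the kernel covariance empirically", {
  # Monte-Carlo check at three fixed times against the closed form
  p0 <- KernelParams(5, 3, 0)
  tt <- list(A = c(6, 9, 13))
  K <- assembleCovariance(tt, "no_shift", p0)
  set.seed(46)
  draws <- MASS::mvrnorm(1e4, mu = rep(0, 3), Sigma = K)
  emp <- cov(draws)
  se3 <- 3 * sqrt((K^2 + tcrossprod(diag(K))) / 1e4)   # 3 standard errors
  expect_true(all(abs(emp - K) < se3))
  expect_equal(K[1, 2], sqExpKernel(6, 9, p0))
})

test_that("three-group shifts follow the alternating-sign scheme", {
  spec <- SimulationSpec("gp", model = "shift", nGroups = 3, nGenes = 200,
                         pointsPerGroup = 2, seed = 47)
  dt <- trueShifts(simulateGP(spec))
  expect_true(all(dt[, "g1"] == 0))
  expect_equal(mean(dt[, "g2"]), 2, tolerance = 0.25)
  expect_equal(mean(dt[, "g3"]), -2, tolerance = 0.25)
  expect_equal(sd(dt[, "g2"]), 1, tolerance = 0.2)
  # no-shift cohorts carry all-zero truth
  dt0 <- trueShifts(simulateGP(SimulationSpec("gp", model = "no_shift",
                                              nGroups = 3, nGenes = 5,
                                              pointsPerGroup = 2, seed = 48)))
  expect_true(all(dt0 == 0))
})

test_that("mspe scores shift recovery", {
  expect_equal(mspe(c(2, 2), c(2, 2)), 0)
  expect_equal(mspe(c(2.1, 1.9), c(2, 2)), 0.01)
  expect_error(mspe(1:3, 1:2), "length")
  m <- mspe(cbind(a = c(2.1, 1.9), b = c(0, 0)),
            cbind(a = c(2, 2), b = c(0, 1)))
  expect_equal(unname(m), c(0.01, 0.5))
})

test_that("residual-variance fractions behave at the extremes", {
  # noiseless gene: fraction 0
  se <- simulatePeriodic(SimulationSpec("periodic", model = "no_shift",
                                        nGenes = 1, pointsPerGroup = 20,
                                        noiseSD = 0, seed = 49))
  expect_equal(unname(residualVarianceFraction(se)$fraction), 0)
  # flat latent signal: the observation is pure noise, fraction 1
  se2 <- simulatePolynomial(SimulationSpec("polynomial", model = "no_shift",
                                           nGenes = 1, pointsPerGroup = 20,
                                           coefficients = c(a = 0, b = 0,
                                                            c = 0),
                                           seed = 50))
  expect_equal(unname(residualVarianceFraction(se2)$fraction), 1)
})

test_that("realized noise fractions match their analytic values", {
  # sine signal variance over a full period is 1/2; noise sd 0.3
  # -> noise fraction 0.09 / 0.59
  se <- simulatePeriodic(SimulationSpec("periodic", model = "no_shift",
                                        nGenes = 100, seed = 51))
  fr <- residualVarianceFraction(se)$summary
  expect_lt(abs(unname(fr["mean"]) - 0.09 / 0.59), 0.01)
  # quadratic: Var(b u) = b^2 25/3, Var(c u^2) = c^2 500/9 for u ~ U(-5, 5);
  # noise variance 9 -> fraction 9 / (9 + 18.75 + 55.56) ~ 0.108
  # quadratic cohorts share one time grid, so a single cohort's realized
  # fraction moves with that grid's draw; average a few independent cohorts
  fr2 <- mean(vapply(52:55, function(sd) {
    se2 <- simulatePolynomial(SimulationSpec("polynomial",
                                             model = "no_shift",
                                             nGenes = 50, seed = sd))
    unname(residualVarianceFraction(se2)$summary["mean"])
  }, 0))
  expect_lt(abs(fr2 - 9 / (9 + 2.25 * 25 / 3 + 500 / 9)), 0.015)
})
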