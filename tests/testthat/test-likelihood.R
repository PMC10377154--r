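test_that("log marginal likelihood matches the standard normal at 1 point", {
  expect_equal(logMarginalLikelihood(0, matrix(1)), -0.5 * log(2 * pi))
  expect_equal(logMarginalLikelihood(1, matrix(1)), -0.5 - 0.5 * log(2 * pi))
  expect_error(logMarginalLikelihood(c(1, 2), matrix(1)), "length")
  expect_error(logMarginalLikelihood(0, matrix(-1)), "positive definite")
})

test_that("factorized likelihood agrees with a naive dense oracle", {
  p <- KernelParams(5, 3, 0.5)
  set.seed(3)
  for (n in c(5, 12, 20)) {
    tt <- list(A = runif(ceiling(n / 2), 5, 15),
               B = runif(floor(n / 2), 5, 15))
    y <- rnorm(n, 0, 3)
    for (kind in c("independence", "no_shift", "shift")) {
      K <- assembleCovariance(tt, kind, p,
                              shifts = c(A = 0, B = 1.3))
      expect_equal(logMarginalLikelihood(y, K), denseLogLik(y, K),
                   tolerance = 1e-8)
    }
  }
})

test_that("compiled objective matches R likelihood and numerical gradient", {
  set.seed(4)
  tt <- list(A = runif(8, 5, 15), B = runif(6, 5, 15))
  y <- rnorm(14)
  y <- y - mean(y)
  p <- list(x = unlist(tt), y = y, g = rep(1:2, c(8, 6)), n = c(8L, 6L))
  theta <- c(log(1.2), log(2.5), log(0.4), 0.7)
  r <- tempshift:::.negLogLik(theta, p, 1L, FALSE, TRUE, 1e-8)
  K <- assembleCovariance(tt, "shift", KernelParams(1.2, 2.5, 0.4),
                          shifts = c(A = 0, B = 0.7))
  expect_equal(-r$value, logMarginalLikelihood(y, K), tolerance = 1e-10)
  # central-difference check of the analytic gradient
  h <- 1e-6
  for (j in seq_along(theta)) {
    tp <- tm <- theta; tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    num <- (tempshift:::.negLogLik(tp, p, 1L, FALSE, TRUE, 1e-8)$value -
            tempshift:::.negLogLik(tm, p, 1L, FALSE, TRUE, 1e-8)$value) /
      (2 * h)
    expect_equal(r$grad[j], num, tolerance = 1e-4)
  }
  # independence model gradient too (no offsets)
  r2 <- tempshift:::.negLogLik(theta[1:3], p, 1L, TRUE, FALSE, 1e-8)
  for (j in 1:3) {
    tp <- tm <- theta[1:3]; tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    num <- (tempshift:::.negLogLik(tp, p, 1L, TRUE, FALSE, 1e-8)$value -
            tempshift:::.negLogLik(tm, p, 1L, TRUE, FALSE, 1e-8)$value) /
      (2 * h)
    expect_equal(r2$grad[j], num, tolerance = 1e-4)
  }
})

test_that("duplicated groups give a zero shift and nested likelihoods", {
  g <- makeDuplicatedGene(n = 15)
  fs <- maximizeLikelihood(g, "shift")
  fn <- maximizeLikelihood(g, "no_shift")
  expect_true(fs@converged)
  expect_equal(unname(fs@shifts["A"]), 0)
  expect_lt(abs(fs@shifts["B"]), 0.05)
  expect_gte(fs@logLik, fn@logLik - 1e-3)
})

test_that("offset estimate matches a dense grid-search oracle", {
  g <- makeSmoothGene(n = 20, shifts = c(0, 1.5), noise = 0.1, seed = 5)
  init <- KernelParams(0.7, 2, 0.1)
  fit <- maximizeLikelihood(g, "shift", init = init,
                            optimizeHyperparams = FALSE,
                            extraStarts = list(c(log(0.7), log(2), log(0.1),
                                                 1.5)))
  # profile the likelihood over the offset on a fine grid, same fixed
  # hyperparameters, using the plain dense route as the oracle
  grid <- seq(-10, 10, by = 0.01)
  y <- unlist(g@expr); y <- y - mean(y)
  ll <- vapply(grid, function(d) {
    K <- assembleCovariance(g@times, "shift", init, shifts = c(0, d))
    logMarginalLikelihood(y, K)
  }, 0)
  expect_lt(abs(fit@shifts["g2"] - grid[which.max(ll)]), 0.011)
})

test_that("shift estimates are translation equivariant", {
  g <- makeSmoothGene(n = 18, shifts = c(0, 1), noise = 0.05, seed = 6)
  f0 <- maximizeLikelihood(g, "shift")
  for (delta in c(-1.2, 0.8)) {
    g2 <- GeneSeries(g@geneId,
                     times = list(g1 = g@times[[1]],
                                  g2 = g@times[[2]] + delta),
                     expr = list(g1 = g@expr[[1]], g2 = g@expr[[2]]))
    f2 <- maximizeLikelihood(g2, "shift")
    expect_equal(unname(f2@shifts["g2"] - f0@shifts["g2"]), delta,
                 tolerance = 0.02)
    expect_equal(f2@logLik, f0@logLik, tolerance = 0.01)
  }
})

test_that("likelihoods are properly nested across random genes", {
  # shift model contains no-shift (dt = 0) and beats independence only
  # when groups genuinely share structure
  for (seed in 1:4) {
    g <- makeSmoothGene(n = 12, shifts = c(0, runif(1, -2, 2)),
                        noise = 0.2, seed = seed)
    r <- fitGene(g)
    expect_gte(r@llrShift, -1e-3)
  }
})
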