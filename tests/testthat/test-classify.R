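test_that("fixed thresholds implement the three-way rule", {
  r <- makeResults(llrShape = c(40, 60, 60), llrShift = c(200, 60, 10))
  out <- classLabels(classifyShifts(r, mode = "fixed",
                                    lambdaShape = 50, lambdaShift = 50))
  expect_equal(unname(out), c("DiffShape", "shift", "no_shift"))
})

test_that("boundary values resolve toward no_shift", {
  r <- makeResults(llrShape = c(50, 60), llrShift = c(200, 50))
  out <- classLabels(classifyShifts(r, mode = "fixed",
                                    lambdaShape = 50, lambdaShift = 50))
  expect_equal(unname(out), c("no_shift", "no_shift"))
})

test_that("adaptive thresholds derive cutoffs from the cohort", {
  # 40 genes engineered to mean(LLRshape) = 100, sd = 20
  base <- rep(c(80, 120), 19)
  shape <- c(base, 55, 120)
  shift <- c(rep(5, 38), 200, 15)
  m <- mean(shape)
  s <- sd(shape)
  r <- makeResults(shape, shift)
  out <- classLabels(classifyShifts(r, mode = "adaptive"))
  # gene at LLRshape = 55: below mean - 2 sd when that cutoff ~ 60
  expect_identical(unname(out[39]), if (55 < m - 2 * s) "DiffShape"
                   else "no_shift")
  expect_identical(unname(out[40]), "shift")   # shape > mean, shift > 10
  r2 <- makeResults(c(120, 80), c(5, 5))
  out2 <- classLabels(classifyShifts(r2, mode = "adaptive"))
  expect_equal(unname(out2), c("no_shift", "no_shift"))
  expect_error(classifyShifts(makeResults(1, 1), mode = "adaptive"),
               "at least 2")
})

test_that("labels partition genes and respect monotonicity", {
  set.seed(10)
  shape <- rnorm(60, 100, 30)
  shift <- abs(rnorm(60, 20, 30))
  r <- classifyShifts(makeResults(shape, shift), mode = "fixed")
  lab <- classLabels(r)
  expect_true(all(lab %in% c("DiffShape", "shift", "no_shift")))
  # raising LLRshift never moves a gene from shift to no_shift
  r2 <- classifyShifts(makeResults(shape, shift + 25), mode = "fixed")
  lab2 <- classLabels(r2)
  expect_false(any(lab == "shift" & lab2 == "no_shift"))
  # adaptive mode is invariant to gene order
  perm <- sample(60)
  r3 <- classifyShifts(makeResults(shape[perm], shift[perm]),
                       mode = "adaptive")
  r4 <- classifyShifts(makeResults(shape, shift), mode = "adaptive")
  expect_equal(unname(classLabels(r3)), unname(classLabels(r4))[perm])
})

test_that("genes with missing LLRs stay unclassified", {
  r <- makeResults(llrShape = c(60, NA), llrShift = c(60, 5))
  out <- classLabels(classifyShifts(r, mode = "fixed"))
  expect_equal(unname(out), c("shift", "unclassified"))
  expect_error(classifyShifts(makeResults(1, 1), mode = "fixed",
                              lambdaShape = NA), "finite")
})
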