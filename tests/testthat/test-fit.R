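test_that("fitGene validates its inputs", {
  g1 <- GeneSeries("solo", times = list(A = 1:5 / 1), expr = list(A = rnorm(5)))
  expect_error(fitGene(g1), "two groups")
  g2 <- makeDuplicatedGene()
  expect_error(fitGene(g2, referenceGroup = "Z"), "reference group")
})

test_that("duplicated groups yield no evidence for a shift", {
  r <- fitGene(makeDuplicatedGene(n = 15))
  expect_lt(abs(r@llrShift), 2)
  expect_lt(abs(r@shifts["B"]), 0.05)
  expect_identical(unname(r@shifts["A"]), 0)
  expect_identical(r@label, "unclassified")
  expect_equal(r@llrShape,
               unname(r@logLik["shift"] - r@logLik["independence"]))
  expect_equal(r@llrShift,
               unname(r@logLik["shift"] - r@logLik["no_shift"]))
})

test_that("fitTempShift runs a small table end to end", {
  set.seed(7)
  tt <- sort(runif(12, 5, 15))
  meta <- data.frame(sample = paste0("s", 1:24),
                     group = rep(c("A", "B"), each = 12),
                     time = c(tt, tt))
  expr <- t(vapply(1:10, function(i)
    sin(2 * pi * c(tt, tt) / 10) + rnorm(24, 0, 0.2), numeric(24)))
  dimnames(expr) <- list(paste0("gene", 1:10), meta$sample)
  res <- fitTempShift(expr, meta)
  expect_s4_class(res, "TempShiftResults")
  expect_equal(nrow(resultsTable(res)), 10)
  expect_identical(referenceGroup(res), "A")
  expect_true(all(shiftEstimates(res)[, "A"] == 0))
  expect_true(all(is.finite(llrShape(res))))
  expect_true(all(llrShift(res) >= -1e-3))
})

test_that("empty gene set gives an empty result", {
  meta <- data.frame(sample = c("s1", "s2", "s3", "s4", "s5", "s6"),
                     group = rep(c("A", "B"), each = 3),
                     time = c(1, 2, 3, 1, 2, 3))
  expr <- matrix(numeric(0), nrow = 0, ncol = 6,
                 dimnames = list(NULL, meta$sample))
  res <- fitTempShift(expr, meta)
  expect_equal(nrow(resultsTable(res)), 0)
})

test_that("metadata mismatches fail before any fitting", {
  expr <- matrix(rnorm(8), 2, 4,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  meta <- data.frame(sample = paste0("s", 1:3), group = "A", time = 1:3)
  expect_error(fitTempShift(expr, meta), "s4")
  meta2 <- data.frame(sample = c("s1", "s2", "s3", "s4", "s4"),
                      group = "A", time = 1:5)
  expect_error(fitTempShift(expr, meta2), "duplicated")
  meta3 <- data.frame(sample = paste0("s", 1:4), group = "A",
                      time = c(1, 2, NA, 4))
  expect_error(fitTempShift(expr, meta3), "non-finite")
})

test_that("missing values are dropped per gene; sparse genes are skipped", {
  set.seed(8)
  tt <- sort(runif(10, 5, 15))
  meta <- data.frame(sample = paste0("s", 1:20),
                     group = rep(c("A", "B"), each = 10),
                     time = c(tt, tt))
  expr <- rbind(
    full = sin(2 * pi * c(tt, tt) / 10) + rnorm(20, 0, 0.1),
    holey = c(NA, sin(2 * pi * tt[-1] / 10), sin(2 * pi * tt / 10)) +
      c(NA, rnorm(19, 0, 0.1)),
    sparse = c(rnorm(2), rep(NA, 8), rnorm(10)))
  colnames(expr) <- meta$sample
  res <- suppressMessages(fitTempShift(expr, meta))
  tab <- resultsTable(res)
  expect_true(is.finite(tab$llrShift[1]))
  expect_true(is.finite(tab$llrShift[2]))   # one sample dropped, still fitted
  expect_true(is.na(tab$llrShift[3]))       # group A kept < 3 points
  expect_identical(tab$label[3], "unclassified")
})

test_that("fits are deterministic and independent of gene order", {
  set.seed(9)
  tt <- sort(runif(10, 5, 15))
  meta <- data.frame(sample = paste0("s", 1:20),
                     group = rep(c("A", "B"), each = 10),
                     time = c(tt, tt))
  expr <- t(vapply(1:4, function(i)
    cos(c(tt, tt) / 2) * i + rnorm(20, 0, 0.1), numeric(20)))
  dimnames(expr) <- list(paste0("gene", 1:4), meta$sample)
  r1 <- fitTempShift(expr, meta)
  r2 <- fitTempShift(expr, meta)
  expect_identical(resultsTable(r1), resultsTable(r2))
  r3 <- fitTempShift(expr[4:1, ], meta)
  expect_equal(resultsTable(r3)$llrShift[4:1], resultsTable(r1)$llrShift)
})
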