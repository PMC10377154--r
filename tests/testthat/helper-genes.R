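## Small deterministic builders used across test files.

# Two- or three-group gene with a shared smooth trajectory and optional
# per-group offsets; tiny sizes keep unit tests fast.
makeSmoothGene <- function(n = 15, shifts = c(0, 0), noise = 0.1,
                           f = function(x) sin(2 * pi * x / 10),
                           seed = 1, range = c(5, 15)) {
  set.seed(seed)
  times <- lapply(seq_along(shifts), function(i)
    sort(runif(n, range[1], range[2])))
  expr <- lapply(seq_along(shifts), function(i)
    f(times[[i]] - shifts[i]) + rnorm(n, 0, noise))
  names(times) <- names(expr) <- paste0("g", seq_along(shifts))
  GeneSeries("smooth", times = times, expr = expr)
}

# A gene whose groups are literal copies of the same observations.
makeDuplicatedGene <- function(n = 15, seed = 2) {
  set.seed(seed)
  tt <- sort(runif(n, 5, 15))
  yy <- sin(2 * pi * tt / 10) + rnorm(n, 0, 0.1)
  GeneSeries("dup", times = list(A = tt, B = tt),
             expr = list(A = yy, B = yy))
}

# Results container built directly from LLR values, for classification tests.
makeResults <- function(llrShape, llrShift, dt = NULL) {
  n <- length(llrShape)
  if (is.null(dt)) dt <- rep(0, n)
  df <- S4Vectors::DataFrame(
    gene_id = paste0("gene", seq_len(n)),
    llrShape = llrShape, llrShift = llrShift,
    dt_g1 = rep(0, n), dt_g2 = dt,
    label = rep("unclassified", n))
  new("TempShiftResults", results = df, referenceGroup = "g1",
      groups = c("g1", "g2"), metadata = list())
}

# Naive dense multivariate-normal log density (explicit inverse and
# determinant); independent oracle for the factorized implementation.
denseLogLik <- function(y, K) {
  -0.5 * drop(t(y) %*% solve(K) %*% y) -
    0.5 * as.numeric(determinant(K, logarithm = TRUE)$modulus) -
    0.5 * length(y) * log(2 * pi)
}
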