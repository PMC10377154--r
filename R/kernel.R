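#' Squared-exponential kernel
#'
#' Evaluates the squared-exponential (Gaussian) covariance function
#' \deqn{k(t_1, t_2) = \sigma_f^2 \exp\{-(t_1 - t_2)^2 / (2 l^2)\}.}
#' The observation-noise term is not included; it enters the covariance
#' matrix on the diagonal only (see \code{\link{assembleCovariance}}).
#'
#' @param t1,t2 numeric time vectors (recycled to a common length).
#' @param params a \code{\link{KernelParams}} object.
#' @return numeric vector of covariances.
#' @examples
#' sqExpKernel(7, 7, KernelParams(5, 3, 0.5))   # sigmaF^2 = 25
#' @export
sqExpKernel <- function(t1, t2, params) {
  stopifnot(is(params, "KernelParams"))
  validObject(params)
  if (!all(is.finite(t1)) || !all(is.finite(t2)))
    stop("'t1' and 't2' must be finite")
  params@sigmaF^2 * exp(-(t1 - t2)^2 / (2 * params@lengthScale^2))
}

#' Covariance matrix of a temporal-expression model
#'
#' Builds the covariance matrix over all pooled observations of a gene under
#' one of the three model structures:
#' \describe{
#'   \item{independence}{block-diagonal: within-group covariance from the
#'     squared-exponential kernel, cross-group covariance identically zero.
#'     Each group's trajectory is an unrelated draw.}
#'   \item{no_shift}{full kernel on the pooled raw times: all groups share
#'     one trajectory.}
#'   \item{shift}{full kernel on adjusted times \eqn{u_i = x_i - \Delta t_i}:
#'     all groups share one trajectory shape evaluated at offset times.}
#' }
#' In all cases \code{noiseSD^2} plus a small jitter
#' (\code{jitter * sigmaF^2}) is added to the diagonal.
#'
#' @param times named list of per-group time vectors (order fixed; the first
#'   group is the conventional reference).
#' @param modelKind \code{"independence"}, \code{"no_shift"} or
#'   \code{"shift"}.
#' @param params a \code{\link{KernelParams}} object.
#' @param shifts named per-group offsets; required for
#'   \code{modelKind = "shift"} (all zeros reproduces the no-shift matrix),
#'   ignored otherwise.
#' @param jitter relative diagonal jitter; the default \code{1e-8} is scaled
#'   by \code{sigmaF^2}.
#' @return an N x N symmetric covariance matrix, N the total number of
#'   pooled observations, with rows ordered group by group.
#' @examples
#' tt <- list(A = c(5, 8), B = c(5, 9))
#' assembleCovariance(tt, "no_shift", KernelParams(5, 3, 0.5))
#' @export
assembleCovariance <- function(times, modelKind = .MODEL_KINDS, params,
                               shifts = NULL, jitter = 1e-8) {
  modelKind <- match.arg(modelKind)
  stopifnot(is(params, "KernelParams"), is.list(times), length(times) >= 1L)
  validObject(params)
  groups <- names(times)
  if (is.null(groups)) groups <- paste0("g", seq_along(times))
  n <- vapply(times, length, 0L)
  if (any(n == 0L)) stop("every group needs at least one time point")
  x <- unlist(times, use.names = FALSE)
  if (!all(is.finite(x))) stop("times must be finite")
  g <- rep(seq_along(times), n)

  if (modelKind == "shift") {
    if (is.null(shifts)) stop("'shifts' is required for the shift model")
    dt <- .alignShifts(shifts, groups)
    u <- x - dt[g]
  } else {
    u <- x
  }
  K <- params@sigmaF^2 * exp(-outer(u, u, "-")^2 / (2 * params@lengthScale^2))
  if (modelKind == "independence")
    K[outer(g, g, "!=")] <- 0
  diag(K) <- diag(K) + params@noiseSD^2 + jitter * params@sigmaF^2
  K
}

## Order a shift vector to match the group order; tolerate unnamed vectors.
.alignShifts <- function(shifts, groups) {
  if (is.null(names(shifts))) {
    if (length(shifts) != length(groups))
      stop("'shifts' must have one entry per group")
    return(as.numeric(shifts))
  }
  miss <- setdiff(groups, names(shifts))
  if (length(miss))
    stop("missing shift for group(s): ", paste(miss, collapse = ", "))
  as.numeric(shifts[groups])
}

#' Exact Gaussian-process log marginal likelihood
#'
#' Log density of the observation vector under a zero-mean multivariate
#' normal with the given covariance matrix,
#' \deqn{-\tfrac12 y^\top K^{-1} y - \tfrac12 \log|K| - \tfrac{N}{2}
#'   \log 2\pi,}
#' evaluated through a Cholesky factorization.
#'
#' @param y numeric observation vector (centered expression values).
#' @param K covariance matrix from \code{\link{assembleCovariance}};
#'   must be symmetric positive definite.
#' @return the log marginal likelihood (a scalar).
#' @examples
#' logMarginalLikelihood(0, matrix(1))   # standard normal at 0
#' @export
logMarginalLikelihood <- function(y, K) {
  y <- as.numeric(y)
  K <- as.matrix(K)
  if (length(y) != nrow(K) || nrow(K) != ncol(K))
    stop("'y' length must match the dimension of 'K'")
  ch <- tryCatch(chol(K), error = function(e)
    stop("covariance matrix is not positive definite: ",
         conditionMessage(e), call. = FALSE))
  a <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  -0.5 * sum(y * a) - sum(log(diag(ch))) - 0.5 * length(y) * log(2 * pi)
}
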