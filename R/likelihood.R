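#' Optimizer control settings
#'
#' @param restartFactors fractions of the observed time span used as
#'   length-scale starting values, one optimizer restart per factor. The
#'   default spans a quarter, a half and the whole time range; starting from
#'   larger length scales guards against overfitting local maxima.
#' @param maxit maximum L-BFGS-B iterations per restart.
#' @param factr L-BFGS-B relative convergence tolerance.
#' @param jitter relative diagonal jitter added as \code{jitter * sigmaF^2}.
#' @param sigmaFloor lower bound on the noise standard deviation, as a
#'   fraction of the data standard deviation; keeps the covariance
#'   nonsingular with replicated or tied time points.
#' @param noiseInitFactor starting noise standard deviation, as a fraction of
#'   the data standard deviation.
#' @param dtScanStep grid step (time units) of the profile walk that
#'   brackets the likelihood basin around zero offset before the shift
#'   model is polished (see \code{\link{maximizeLikelihood}}). Set to 0
#'   to disable bracketing and optimize over the full offset range.
#' @param basinDepth hysteresis depth (log-likelihood units) of the profile
#'   walk: the basin boundary is declared where the pairwise profile falls
#'   this far below its running maximum. Deep valleys -- severe
#'   misalignments, period aliases -- terminate the walk; shallow noise
#'   dips do not.
#' @param aliasWindow when several restart optima lie within this many
#'   log-likelihood units of the best one -- near-equivalent alignments,
#'   as when a trajectory is periodic and an offset and its period alias
#'   explain the data almost equally well -- the smallest-offset optimum
#'   is reported. Decisively better optima (beyond the window) always win.
#' @return a named list of settings for \code{\link{maximizeLikelihood}}.
#' @export
tsControl <- function(restartFactors = c(0.25, 0.5, 1), maxit = 200L,
                      factr = 1e7, jitter = 1e-8, sigmaFloor = 1e-4,
                      noiseInitFactor = 0.2, dtScanStep = 0.25,
                      basinDepth = 15, aliasWindow = 10) {
  stopifnot(length(restartFactors) >= 1L, all(restartFactors > 0),
            maxit >= 1L, factr > 0, jitter >= 0, sigmaFloor > 0,
            dtScanStep >= 0, basinDepth > 0, aliasWindow >= 0)
  list(restartFactors = restartFactors, maxit = as.integer(maxit),
       factr = factr, jitter = jitter, sigmaFloor = sigmaFloor,
       noiseInitFactor = noiseInitFactor, dtScanStep = dtScanStep,
       basinDepth = basinDepth, aliasWindow = aliasWindow)
}

## Profile each non-reference group's offset against the reference group
## on a full grid (hyperparameters fixed at a fit of the reference group's
## own data). Among profile peaks within `window` log-units of the best
## one -- near-equivalent alignments, e.g. period aliases -- the smallest
## offset is taken as the canonical alignment; the returned box brackets
## its likelihood basin (profile above peak - depth) so the joint polish
## cannot drift into a different mode.
.dtProfile <- function(p, ref, sf, l, s, span, step, depth, window,
                       jitter) {
  nG <- length(p$n)
  lo <- rep(-span, nG); hi <- rep(span, nG); init <- rep(0, nG)
  refIdx <- which(p$g == ref)
  # groups already profiled join the reference block at their aligned
  # times, so later groups are located against all available data
  refX <- p$x[refIdx]; refY <- p$y[refIdx]
  grid <- seq(-span, span, by = step)
  for (i in seq_len(nG)[-ref]) {
    gIdx <- which(p$g == i)
    x <- c(refX, p$x[gIdx]); y <- c(refY, p$y[gIdx])
    shiftable <- c(rep(FALSE, length(refX)), rep(TRUE, length(gIdx)))
    ll <- as.numeric(.pairProfileGrid(x, y, as.integer(shiftable), grid,
                                      sf, l, s, jitter))
    n <- length(grid)
    isPeak <- vapply(seq_len(n), function(j) {
      is.finite(ll[j]) &&
        (j == 1L || ll[j] >= ll[j - 1L]) && (j == n || ll[j] >= ll[j + 1L])
    }, TRUE)
    peaks <- which(isPeak)
    if (length(peaks) == 0L) peaks <- which.max(ll)
    near <- peaks[ll[peaks] >= max(ll[peaks]) - window]
    # smallest offset among near-equal peaks. Peak positions are refined
    # by parabolic interpolation before comparing magnitudes: an offset
    # and its period alias lie symmetrically about half the period, so
    # with accurate positions the smaller-magnitude member is the
    # canonical (sub-half-period) alignment; grid-resolution error on
    # that comparison would otherwise decide it arbitrarily.
    refine <- vapply(near, function(j) {
      if (j <= 1L || j >= n) return(grid[j])
      den <- ll[j - 1L] - 2 * ll[j] + ll[j + 1L]
      if (!is.finite(den) || den >= 0) return(grid[j])
      grid[j] + 0.5 * step * (ll[j - 1L] - ll[j + 1L]) / den
    }, 0)
    pick <- which.min(abs(refine))
    top <- near[pick]
    init[i] <- refine[pick]
    refX <- c(refX, p$x[gIdx] - init[i])
    refY <- c(refY, p$y[gIdx])
    jlo <- top
    while (jlo > 1L && ll[jlo - 1L] > ll[top] - depth) jlo <- jlo - 1L
    jhi <- top
    while (jhi < n && ll[jhi + 1L] > ll[top] - depth) jhi <- jhi + 1L
    lo[i] <- grid[jlo]; hi[i] <- grid[jhi]
  }
  list(lo = lo[-ref], hi = hi[-ref], init = init[-ref])
}

## Pooled representation of a GeneSeries: x, y, integer group index, sizes.
.pooled <- function(gene) {
  n <- vapply(gene@times, length, 0L)
  list(x = unlist(gene@times, use.names = FALSE),
       y = unlist(gene@expr, use.names = FALSE),
       g = rep(seq_along(n), n), n = n, groups = gene@groups)
}

## Negative log marginal likelihood and gradient at
## theta = (log sigmaF, log l, log sigma [, dt_nonref...]).
.negLogLik <- function(theta, p, ref, blockDiag, withShift, jitter) {
  .gpNegLogLik(theta, p$x, p$y, as.integer(p$g), length(p$n), as.integer(ref),
               blockDiag, withShift, jitter)
}

#' Maximize the GP marginal likelihood of one model for one gene
#'
#' Fits one of the three temporal-expression models by maximizing the exact
#' Gaussian-process marginal likelihood with a quasi-Newton (L-BFGS-B)
#' optimizer over log-transformed kernel hyperparameters and, for the shift
#' model, the raw per-group offsets \eqn{\Delta t}. The gene's expression is
#' centered by its pooled mean before fitting (the GP prior is zero-mean);
#' the subtracted mean is recorded in the returned fit. Several restarts
#' with increasing length-scale starting values are run and the best
#' maximized likelihood kept.
#'
#' The shift-model likelihood is multimodal in \eqn{\Delta t}: besides the
#' basin of the dominant alignment there are degenerate modes that slide a
#' group mostly off the data support, and, for periodic trajectories,
#' period aliases of the true offset. The reported offset is therefore the
#' optimum of the likelihood basin around zero offset: before the joint
#' polish, the pairwise profile of each non-reference group against the
#' reference is walked outward from zero (step \code{dtScanStep}) and the
#' basin boundary declared where the profile drops \code{basinDepth}
#' log-units below its running maximum; the joint optimization is then
#' box-constrained to that basin and seeded at its profile argmax.
#' Offsets are never allowed beyond plus or minus the pooled time span.
#'
#' @param gene a \code{\link{GeneSeries}}.
#' @param modelKind \code{"independence"}, \code{"no_shift"} or
#'   \code{"shift"}.
#' @param referenceGroup label of the group whose offset is fixed at 0;
#'   default: the first group.
#' @param init optional \code{\link{KernelParams}} starting values; the
#'   length scale is still varied across restarts unless
#'   \code{optimizeHyperparams = FALSE}.
#' @param control settings from \code{\link{tsControl}}.
#' @param optimizeHyperparams if \code{FALSE}, hyperparameters are held
#'   fixed at \code{init} and only \eqn{\Delta t} is optimized (shift model;
#'   the other models are simply evaluated at \code{init}).
#' @param extraStarts optional list of additional full starting vectors
#'   \code{(log sigmaF, log l, log sigma, dt...)}, run as extra restarts.
#' @return a \code{\link{ModelFit}}. A fit for which no restart converged is
#'   returned with \code{converged = FALSE}, not raised as an error.
#' @export
maximizeLikelihood <- function(gene, modelKind = .MODEL_KINDS,
                               referenceGroup = NULL, init = NULL,
                               control = tsControl(),
                               optimizeHyperparams = TRUE,
                               extraStarts = list()) {
  modelKind <- match.arg(modelKind)
  stopifnot(is(gene, "GeneSeries"))
  validObject(gene)
  p <- .pooled(gene)
  if (is.null(referenceGroup)) referenceGroup <- p$groups[1L]
  ref <- match(referenceGroup, p$groups)
  if (is.na(ref)) stop("reference group '", referenceGroup, "' not found")
  withShift <- modelKind == "shift"
  blockDiag <- modelKind == "independence"
  nGroups <- length(p$n)
  if (withShift && nGroups < 2L)
    stop("the shift model needs at least two groups")

  center <- mean(p$y)
  p$y <- p$y - center
  sdy <- max(sd(p$y), 1e-8)
  span <- max(diff(range(p$x)), 1e-8)
  nDt <- if (withShift) nGroups - 1L else 0L

  if (is.null(init)) {
    base <- c(log(sdy), NA_real_, log(max(control$noiseInitFactor * sdy,
                                          control$sigmaFloor * sdy)))
  } else {
    stopifnot(is(init, "KernelParams"))
    base <- log(c(init@sigmaF, init@lengthScale,
                  max(init@noiseSD, control$sigmaFloor * sdy)))
  }

  lower <- c(log(1e-4 * sdy), log(1e-3 * span), log(control$sigmaFloor * sdy),
             rep(-span, nDt))
  upper <- c(log(1e4 * sdy), log(1e3 * span), log(1e4 * sdy), rep(span, nDt))

  evalAt <- function(theta) {
    .negLogLik(theta, p, ref, blockDiag, withShift, control$jitter)
  }

  if (!optimizeHyperparams && is.null(init))
    stop("'init' is required when optimizeHyperparams = FALSE")

  dtInit <- rep(0, nDt)
  dtLo <- rep(-span, nDt); dtHi <- rep(span, nDt)
  if (withShift && optimizeHyperparams && control$dtScanStep > 0 &&
      nDt > 0L) {
    # hyperparameters for profiling, fitted on the reference group's own
    # data (whose trajectory is observed at unshifted times regardless of
    # the other groups' offsets)
    refIdx <- which(p$g == ref)
    pr <- list(x = p$x[refIdx], y = p$y[refIdx],
               g = rep(1L, length(refIdx)), n = length(refIdx))
    preCache <- new.env(parent = emptyenv())
    fnP <- function(z) {
      r <- .negLogLik(z, pr, 1L, FALSE, FALSE, control$jitter)
      assign("grad", r$grad, envir = preCache)
      r$value
    }
    grP <- function(z) get("grad", envir = preCache)
    th0 <- base
    if (is.na(th0[2L])) th0[2L] <- log(0.5 * span)
    preOpt <- tryCatch(
      optim(th0, fnP, grP, method = "L-BFGS-B",
            lower = lower[1:3], upper = upper[1:3],
            control = list(maxit = 60L, factr = control$factr)),
      error = function(e) list(par = th0))
    hp <- exp(preOpt$par)
    prof <- .dtProfile(p, ref, hp[1L], hp[2L], hp[3L], span,
                       control$dtScanStep, control$basinDepth,
                       control$aliasWindow, control$jitter)
    dtInit <- prof$init
    dtLo <- prof$lo; dtHi <- prof$hi
  }

  starts <- list()
  boxed <- logical()
  if (optimizeHyperparams) {
    for (f in control$restartFactors) {
      th <- base
      if (is.na(th[2L]) || length(control$restartFactors) > 1L)
        th[2L] <- log(f * span)
      starts[[length(starts) + 1L]] <- c(th, dtInit)
      boxed <- c(boxed, TRUE)
    }
  } else {
    starts[[1L]] <- c(base, rep(0, nDt))
    boxed <- FALSE
  }
  for (s in extraStarts) {
    starts[[length(starts) + 1L]] <- s
    boxed <- c(boxed, FALSE)   # caller-provided starts explore freely
  }

  free <- if (optimizeHyperparams) seq_len(3L + nDt) else
    if (nDt > 0L) 3L + seq_len(nDt) else integer()

  runs <- vector("list", length(starts))
  for (si in seq_along(starts)) {
    th0 <- starts[[si]]
    if (length(free) == 0L) {            # nothing to optimize: evaluate
      v <- evalAt(th0)$value
      o <- list(par = th0, value = v, convergence = 0L)
    } else {
      gradCache <- new.env(parent = emptyenv())
      fn <- function(z) {
        th <- th0; th[free] <- z
        r <- evalAt(th)
        assign("grad", r$grad[free], envir = gradCache)
        r$value
      }
      gr <- function(z) get("grad", envir = gradCache)
      lw <- lower; up <- upper
      if (nDt > 0L && boxed[si]) {
        lw[3L + seq_len(nDt)] <- dtLo
        up[3L + seq_len(nDt)] <- dtHi
      }
      o <- tryCatch(
        optim(th0[free], fn, gr, method = "L-BFGS-B",
              lower = lw[free], upper = up[free],
              control = list(maxit = control$maxit, factr = control$factr)),
        error = function(e) list(par = th0[free], value = Inf,
                                 convergence = 99L))
      z <- o$par; th <- th0; th[free] <- z; o$par <- th
    }
    runs[[si]] <- o
  }
  vals <- vapply(runs, `[[`, 0, "value")
  best <- runs[[which.min(vals)]]
  if (withShift && length(runs) > 1L) {
    # near-equivalent alignments (within aliasWindow of the best run)
    # resolve to the profile's canonical choice: among eligible runs the
    # box-constrained ones seeded at the profiled offset take precedence,
    # so an unboxed run wins only when it is decisively better. The
    # starting value of any caller-provided start (the zero-offset warm
    # start of the enclosing model comparison, whose value is the
    # no-shift likelihood) caps how much likelihood the preference may
    # give up, keeping the model nesting intact.
    capExtra <- if (length(extraStarts))
      min(vapply(extraStarts, function(th) evalAt(th)$value, 0)) else Inf
    elig <- which(vals <= min(capExtra + 1e-6,
                              min(vals) + control$aliasWindow))
    if (length(elig) > 1L) {
      eboxed <- elig[boxed[elig]]
      if (length(eboxed)) {
        best <- runs[[eboxed[which.min(vals[eboxed])]]]
      } else {
        nrm <- vapply(elig, function(j) sum(runs[[j]]$par[-(1:3)]^2), 0)
        best <- runs[[elig[which.min(nrm)]]]
      }
    }
  }

  ok <- is.finite(best$value) && best$value < 1e9 && best$convergence %in%
    c(0L, 1L)  # 1 = maxit reached; still a usable (flagged) optimum
  shifts <- numeric()
  if (withShift) {
    shifts <- rep(0, nGroups)
    shifts[-ref] <- best$par[-(1:3)]
    names(shifts) <- p$groups
  }
  new("ModelFit", kind = modelKind,
      logLik = if (is.finite(best$value) && best$value < 1e9)
        -best$value else NA_real_,
      params = KernelParams(exp(best$par[1L]), exp(best$par[2L]),
                            exp(best$par[3L])),
      shifts = shifts, center = center,
      converged = ok && best$convergence == 0L,
      restarts = length(starts))
}
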