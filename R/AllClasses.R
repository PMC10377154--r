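#' @import methods
#' @importFrom stats optim rnorm runif sd var lm setNames
#' @importFrom utils packageVersion read.delim write.table
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData rowData<- colData<-
#' @useDynLib tempshift, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.MODEL_KINDS <- c("independence", "no_shift", "shift")
.CLASS_LABELS <- c("DiffShape", "shift", "no_shift", "unclassified")

#' Squared-exponential kernel hyperparameters
#'
#' Holds the three hyperparameters of the noisy squared-exponential
#' (Gaussian) kernel: the signal amplitude \eqn{\sigma_f} (expression units),
#' the length scale \eqn{l} (time units) governing trajectory smoothness, and
#' the observation noise standard deviation \eqn{\sigma} (expression units).
#'
#' @slot sigmaF positive amplitude \eqn{\sigma_f}.
#' @slot lengthScale positive length scale \eqn{l}.
#' @slot noiseSD non-negative noise standard deviation \eqn{\sigma}.
#' @export
setClass("KernelParams",
  representation(sigmaF = "numeric", lengthScale = "numeric",
                 noiseSD = "numeric"))

setValidity("KernelParams", function(object) {
  msg <- character()
  for (s in c("sigmaF", "lengthScale", "noiseSD")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msg) == 0L) {
    if (object@sigmaF <= 0) msg <- c(msg, "'sigmaF' must be > 0")
    if (object@lengthScale <= 0) msg <- c(msg, "'lengthScale' must be > 0")
    if (object@noiseSD < 0) msg <- c(msg, "'noiseSD' must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' @param sigmaF,lengthScale,noiseSD see slot descriptions.
#' @return A \code{KernelParams} object.
#' @examples
#' KernelParams(sigmaF = 5, lengthScale = 3, noiseSD = 0.5)
#' @rdname KernelParams-class
#' @export
KernelParams <- function(sigmaF, lengthScale, noiseSD) {
  new("KernelParams", sigmaF = as.numeric(sigmaF),
      lengthScale = as.numeric(lengthScale), noiseSD = as.numeric(noiseSD))
}

setMethod("show", "KernelParams", function(object) {
  cat(sprintf("KernelParams: sigmaF = %g, lengthScale = %g, noiseSD = %g\n",
              object@sigmaF, object@lengthScale, object@noiseSD))
})

#' One gene's multi-group time series
#'
#' Per-group observation times and expression values for a single gene.
#' Groups may have different numbers of observations and unmatched time
#' points; the first group is the default reference.
#'
#' @slot geneId single gene identifier.
#' @slot groups unique group labels, in a fixed order.
#' @slot times list of numeric time vectors, one per group.
#' @slot expr list of numeric expression vectors, parallel to \code{times}.
#' @export
setClass("GeneSeries",
  representation(geneId = "character", groups = "character",
                 times = "list", expr = "list"))

setValidity("GeneSeries", function(object) {
  msg <- character()
  if (length(object@geneId) != 1L) msg <- c(msg, "'geneId' must be length 1")
  g <- length(object@groups)
  if (g < 1L) msg <- c(msg, "at least one group is required")
  if (anyDuplicated(object@groups)) msg <- c(msg, "group labels must be unique")
  if (length(object@times) != g || length(object@expr) != g)
    msg <- c(msg, "'times' and 'expr' must have one element per group")
  else for (i in seq_len(g)) {
    ti <- object@times[[i]]; yi <- object@expr[[i]]
    if (length(ti) == 0L)
      msg <- c(msg, sprintf("group '%s' has no observations", object@groups[i]))
    if (length(ti) != length(yi))
      msg <- c(msg, sprintf("group '%s': times and expr lengths differ",
                            object@groups[i]))
    if (!all(is.finite(ti)))
      msg <- c(msg, sprintf("group '%s': non-finite times", object@groups[i]))
  }
  if (length(msg)) msg else TRUE
})

#' @param geneId,groups,times,expr see slot descriptions; \code{times} and
#'   \code{expr} may be named lists, in which case names define the groups.
#' @return A \code{GeneSeries} object.
#' @rdname GeneSeries-class
#' @export
GeneSeries <- function(geneId, times, expr, groups = names(times)) {
  if (is.null(groups)) groups <- paste0("g", seq_along(times))
  new("GeneSeries", geneId = as.character(geneId),
      groups = as.character(groups),
      times = lapply(unname(times), as.numeric),
      expr = lapply(unname(expr), as.numeric))
}

setMethod("show", "GeneSeries", function(object) {
  n <- vapply(object@times, length, 0L)
  cat(sprintf("GeneSeries '%s': %d group(s) [%s]\n", object@geneId,
              length(object@groups),
              paste(sprintf("%s: n=%d", object@groups, n), collapse = ", ")))
})

#' A fitted temporal-expression model for one gene
#'
#' @slot kind one of \code{"independence"}, \code{"no_shift"}, \code{"shift"}.
#' @slot logLik maximized log marginal likelihood (\code{NA} if the fit
#'   failed to converge).
#' @slot params \code{KernelParams} at the optimum.
#' @slot shifts named per-group time offsets; the reference entry is exactly
#'   0. Empty for non-shift models.
#' @slot center pooled expression mean subtracted before fitting.
#' @slot converged logical convergence flag.
#' @slot restarts number of optimizer restarts used.
#' @export
setClass("ModelFit",
  representation(kind = "character", logLik = "numeric",
                 params = "KernelParams", shifts = "numeric",
                 center = "numeric", converged = "logical",
                 restarts = "integer"))

setValidity("ModelFit", function(object) {
  msg <- character()
  if (!object@kind %in% .MODEL_KINDS)
    msg <- c(msg, sprintf("'kind' must be one of %s",
                          paste(.MODEL_KINDS, collapse = ", ")))
  if (isTRUE(object@converged) && !is.finite(object@logLik))
    msg <- c(msg, "a converged fit must have finite logLik")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit [%s]: logLik = %.4f, converged = %s\n", object@kind,
              object@logLik, object@converged))
  show(object@params)
  if (length(object@shifts))
    cat("  shifts:", paste(sprintf("%s = %.4g", names(object@shifts),
                                   object@shifts), collapse = ", "), "\n")
})

#' Per-gene model-comparison result
#'
#' Log marginal likelihoods of the three fitted models, the two
#' log-likelihood ratios used for classification, the estimated per-group
#' time shifts, and the class label (set by \code{\link{classifyShifts}}).
#'
#' @slot geneId gene identifier.
#' @slot logLik named numeric: log marginal likelihoods of the
#'   \code{independence}, \code{no_shift} and \code{shift} models (\code{NA}
#'   for models not fitted or not converged).
#' @slot llrShape \code{logLik[shift] - logLik[independence]}; low values
#'   flag trajectories of genuinely different shape.
#' @slot llrShift \code{logLik[shift] - logLik[no_shift]}; high values flag
#'   genuine temporal offsets.
#' @slot shifts named per-group time shift estimates (reference = 0).
#' @slot fits list of \code{ModelFit} objects, by model kind.
#' @slot label one of \code{"DiffShape"}, \code{"shift"}, \code{"no_shift"},
#'   \code{"unclassified"}.
#' @export
setClass("GeneResult",
  representation(geneId = "character", logLik = "numeric",
                 llrShape = "numeric", llrShift = "numeric",
                 shifts = "numeric", fits = "list", label = "character"))

setValidity("GeneResult", function(object) {
  msg <- character()
  if (!object@label %in% .CLASS_LABELS)
    msg <- c(msg, "invalid class label")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneResult", function(object) {
  cat(sprintf("GeneResult '%s': LLRshape = %.3f, LLRshift = %.3f [%s]\n",
              object@geneId, object@llrShape, object@llrShift, object@label))
  if (length(object@shifts))
    cat("  shifts:", paste(sprintf("%s = %.4g", names(object@shifts),
                                   object@shifts), collapse = ", "), "\n")
})

#' Results of a multi-gene temporal-shift analysis
#'
#' A container with one row per analyzed gene, produced by
#' \code{\link{fitTempShift}} and labeled by \code{\link{classifyShifts}}.
#'
#' @slot results a \code{DataFrame} with per-gene log likelihoods, LLRs,
#'   shift estimates, kernel parameters, convergence flags and labels.
#' @slot referenceGroup reference group label (its shift is fixed at 0).
#' @slot groups all group labels, reference first is not required.
#' @slot metadata run metadata (settings, seed, package version, thresholds).
#' @export
setClass("TempShiftResults",
  representation(results = "DataFrame", referenceGroup = "character",
                 groups = "character", metadata = "list"))

setMethod("show", "TempShiftResults", function(object) {
  cat(sprintf("TempShiftResults: %d gene(s), %d group(s), reference '%s'\n",
              nrow(object@results), length(object@groups),
              object@referenceGroup))
  lab <- object@results$label
  if (!is.null(lab) && !all(lab == "unclassified")) {
    tb <- table(factor(lab, levels = .CLASS_LABELS))
    cat("  labels:", paste(sprintf("%s = %d", names(tb), tb),
                           collapse = ", "), "\n")
  }
})

#' @describeIn TempShiftResults-class per-gene results as a \code{DataFrame}.
#' @param x a \code{TempShiftResults} object.
#' @export
resultsTable <- function(x) {
  stopifnot(is(x, "TempShiftResults"))
  x@results
}

#' @describeIn TempShiftResults-class vector of LLRshape values, named by gene.
#' @export
llrShape <- function(x) {
  stopifnot(is(x, "TempShiftResults"))
  setNames(x@results$llrShape, x@results$gene_id)
}

#' @describeIn TempShiftResults-class vector of LLRshift values, named by gene.
#' @export
llrShift <- function(x) {
  stopifnot(is(x, "TempShiftResults"))
  setNames(x@results$llrShift, x@results$gene_id)
}

#' @describeIn TempShiftResults-class matrix of estimated time shifts
#'   (genes x groups; the reference column is all zero).
#' @export
shiftEstimates <- function(x) {
  stopifnot(is(x, "TempShiftResults"))
  cols <- paste0("dt_", x@groups)
  m <- as.matrix(as.data.frame(x@results[, cols, drop = FALSE]))
  dimnames(m) <- list(x@results$gene_id, x@groups)
  m
}

#' @describeIn TempShiftResults-class per-gene class labels, named by gene.
#' @export
classLabels <- function(x) {
  stopifnot(is(x, "TempShiftResults"))
  setNames(x@results$label, x@results$gene_id)
}

#' @describeIn TempShiftResults-class the reference group label.
#' @export
referenceGroup <- function(x) {
  stopifnot(is(x, "TempShiftResults"))
  x@referenceGroup
}
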