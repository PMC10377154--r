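#' Classify genes as DiffShape, shift or no-shift
#'
#' Assigns each gene one of three labels from its two log-likelihood ratios.
#'
#' \strong{Fixed mode} uses user-chosen cutoffs \eqn{\Lambda_{shape}} and
#' \eqn{\Lambda_{shift}} (both 50 by default, suited to large multi-area
#' analyses of pre-selected dynamic genes):
#' \itemize{
#'   \item \code{DiffShape} if \code{LLRshape} < \eqn{\Lambda_{shape}};
#'   \item \code{shift} if \code{LLRshape} > \eqn{\Lambda_{shape}} and
#'     \code{LLRshift} > \eqn{\Lambda_{shift}};
#'   \item \code{no_shift} otherwise.
#' }
#'
#' \strong{Adaptive mode} derives the shape cutoff from the analyzed cohort
#' itself (useful when no pre-selection was applied and LLR scales differ):
#' \itemize{
#'   \item \code{DiffShape} if \code{LLRshape} < mean(\code{LLRshape})
#'     \eqn{- 2} sd(\code{LLRshape});
#'   \item \code{shift} if \code{LLRshape} > mean(\code{LLRshape}) and
#'     \code{LLRshift} > \eqn{\Lambda_{shift}} (default 10);
#'   \item \code{no_shift} otherwise.
#' }
#' The sd is the sample standard deviation (n - 1 denominator), taken over
#' all genes with defined LLRs. Values falling exactly on a cutoff are
#' resolved toward the less extreme class (\code{no_shift}). Genes with
#' missing LLRs are labeled \code{unclassified}.
#'
#' @param x a \code{\link{TempShiftResults}}.
#' @param mode \code{"fixed"} or \code{"adaptive"}.
#' @param lambdaShape fixed-mode cutoff on \code{LLRshape}.
#' @param lambdaShift cutoff on \code{LLRshift}; defaults to 50 in fixed
#'   mode and 10 in adaptive mode.
#' @return the input \code{TempShiftResults} with labels filled in and the
#'   thresholds recorded in its metadata.
#' @export
classifyShifts <- function(x, mode = c("fixed", "adaptive"),
                           lambdaShape = 50,
                           lambdaShift = if (mode[1L] == "fixed") 50 else 10) {
  stopifnot(is(x, "TempShiftResults"))
  mode <- match.arg(mode)
  shape <- x@results$llrShape
  shift <- x@results$llrShift
  ok <- is.finite(shape) & is.finite(shift)

  if (mode == "adaptive") {
    if (sum(ok) < 2L)
      stop("adaptive thresholds need at least 2 genes with defined LLRs")
    m <- mean(shape[ok]); s <- sd(shape[ok])
    shapeCut <- m - 2 * s
    shiftGate <- m
  } else {
    if (!is.finite(lambdaShape) || !is.finite(lambdaShift))
      stop("fixed mode requires finite lambdaShape and lambdaShift")
    shapeCut <- lambdaShape
    shiftGate <- lambdaShape
  }

  label <- rep("unclassified", length(shape))
  label[ok] <- "no_shift"
  label[ok & shape < shapeCut] <- "DiffShape"
  label[ok & shape > shiftGate & shift > lambdaShift] <- "shift"
  x@results$label <- label
  x@metadata$classification <- list(mode = mode, shapeCut = shapeCut,
                                    shiftGate = shiftGate,
                                    lambdaShift = lambdaShift,
                                    tieBreak = "toward no_shift")
  x
}
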