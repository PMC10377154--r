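#' Variance explained by a cubic trend in time
#'
#' Ordinary least squares fit of expression on \{1, t, t^2, t^3\}, pooling
#' all groups, and its coefficient of determination. Used to pre-select
#' temporally dynamic genes before model fitting: the larger the R^2, the
#' stronger the relationship between expression and developmental time.
#' Genes with constant expression are assigned R^2 = 0 by convention, so
#' they are never retained.
#'
#' @param expression numeric expression vector.
#' @param time numeric time vector, same length; must not be constant.
#' @return R^2 in [0, 1].
#' @examples
#' tt <- 1:10
#' cubicR2(2 + tt - 0.5 * tt^3, tt)   # exactly cubic: 1
#' @export
cubicR2 <- function(expression, time) {
  expression <- as.numeric(expression); time <- as.numeric(time)
  keep <- is.finite(expression) & is.finite(time)
  expression <- expression[keep]; time <- time[keep]
  if (length(expression) < 5L)
    stop("at least 5 observations are required")
  if (diff(range(time)) == 0) stop("time vector is constant")
  if (var(expression) == 0) return(0)
  fit <- lm(expression ~ time + I(time^2) + I(time^3))
  sse <- sum(fit$residuals^2)
  sst <- sum((expression - mean(expression))^2)
  max(0, min(1, 1 - sse / sst))
}

#' Pre-select temporally dynamic genes by cubic regression
#'
#' Screens a genes x samples table for genes whose expression changes with
#' time, retaining those with cubic-model \code{R^2} above a threshold
#' (default 0.5). One regression per gene is fitted on all samples pooled
#' across groups. Ages given as raw post-conceptional days can be
#' log2-transformed first, the customary developmental time coordinate.
#'
#' @param x a \code{SummarizedExperiment} (expression in the first assay,
#'   \code{colData$time}) or a numeric matrix.
#' @param metadata for the matrix method: \code{data.frame} with columns
#'   \code{sample}, \code{group}, \code{time}.
#' @param threshold retain genes with \code{R^2} strictly above this value,
#'   in [0, 1].
#' @param log2Days apply \code{log2} to the time coordinate first (times
#'   then must be positive days).
#' @return a list with \code{retained} (character vector of gene ids) and
#'   \code{r2} (named per-gene R^2).
#' @export
filterDynamicGenes <- function(x, metadata = NULL, threshold = 0.5,
                               log2Days = FALSE) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (is(x, "SummarizedExperiment")) {
    expr <- as.matrix(assay(x, 1L))
    time <- as.numeric(colData(x)$time)
  } else {
    expr <- as.matrix(x)
    .checkMetadata(expr, metadata)
    time <- as.numeric(metadata$time[match(colnames(expr), metadata$sample)])
  }
  if (log2Days) {
    if (any(time <= 0)) stop("log2Days requires positive times (days)")
    time <- log2(time)
  }
  r2 <- vapply(seq_len(nrow(expr)), function(i)
    cubicR2(expr[i, ], time), 0)
  ids <- rownames(expr)
  if (is.null(ids)) ids <- sprintf("gene%d", seq_len(nrow(expr)))
  names(r2) <- ids
  retained <- ids[r2 > threshold]
  message(length(retained), " of ", length(ids),
          " gene(s) retained at R2 > ", threshold)
  list(retained = retained, r2 = r2)
}
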