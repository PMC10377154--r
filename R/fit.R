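#' Fit the three temporal-expression models to one gene
#'
#' Fits the independence, no-shift and shift models to a single gene and
#' computes the two log-likelihood ratios used for classification:
#' \deqn{LLR_{shape} = \log L_{shift} - \log L_{independence}, \quad
#'       LLR_{shift} = \log L_{shift} - \log L_{no\mbox{-}shift}.}
#' Low \code{LLRshape} flags groups whose trajectories have genuinely
#' different shapes; high \code{LLRshift} flags a genuine temporal offset
#' of a shared trajectory. Within each model one kernel hyperparameter
#' triple is shared across groups, so the comparison contrasts correlation
#' structure rather than model flexibility. Because the no-shift model is
#' the \eqn{\Delta t = 0} restriction of the shift model, the optimum of
#' the no-shift fit seeds an extra restart of the shift fit, which keeps
#' the maximized likelihoods properly nested (\code{LLRshift >= 0} up to
#' optimizer tolerance).
#'
#' The class label is left \code{"unclassified"}; labeling is a separate
#' stage (\code{\link{classifyShifts}}).
#'
#' @param gene a \code{\link{GeneSeries}} with at least two groups.
#' @param referenceGroup label of the reference group (offset fixed at 0);
#'   default: the gene's first group.
#' @param models subset of models to fit; LLRs involving an unfitted model
#'   are \code{NA}.
#' @param control settings from \code{\link{tsControl}}.
#' @return a \code{\link{GeneResult}}.
#' @examples
#' tt <- seq(5, 15, length.out = 20)
#' g <- GeneSeries("ex", times = list(A = tt, B = tt),
#'                 expr = list(A = sin(tt), B = sin(tt)))
#' fitGene(g)   # duplicated groups: LLRshift ~ 0, shift ~ 0
#' @export
fitGene <- function(gene, referenceGroup = NULL,
                    models = .MODEL_KINDS, control = tsControl()) {
  stopifnot(is(gene, "GeneSeries"))
  validObject(gene)
  models <- match.arg(models, several.ok = TRUE)
  if (length(gene@groups) < 2L)
    stop("gene '", gene@geneId, "': at least two groups are required")
  if (is.null(referenceGroup)) referenceGroup <- gene@groups[1L]
  if (!referenceGroup %in% gene@groups)
    stop("reference group '", referenceGroup, "' not found in gene '",
         gene@geneId, "'")

  fits <- list()
  logLik <- setNames(rep(NA_real_, 3L), .MODEL_KINDS)
  for (kind in c("independence", "no_shift")) {
    if (!kind %in% models) next
    fits[[kind]] <- maximizeLikelihood(gene, kind, referenceGroup,
                                       control = control)
    logLik[kind] <- fits[[kind]]@logLik
  }
  if ("shift" %in% models) {
    nDt <- length(gene@groups) - 1L
    hypStart <- function(fit, dt = rep(0, nDt))
      c(log(fit@params@sigmaF), log(fit@params@lengthScale),
        log(fit@params@noiseSD), dt)
    extra <- list()
    ns <- fits[["no_shift"]]
    if (!is.null(ns) && is.finite(ns@logLik))
      extra <- list(hypStart(ns))
    sf <- maximizeLikelihood(gene, "shift", referenceGroup,
                             control = control, extraStarts = extra)
    # the two fits explore the shared hyperparameter surface along
    # different paths; hand the shift optimum's hyperparameters back to
    # the no-shift fit, and if that improves it, re-polish the shift fit
    # from the improved optimum so the nesting LLRshift >= 0 is kept
    if (!is.null(ns) && is.finite(ns@logLik) && is.finite(sf@logLik)) {
      ns2 <- maximizeLikelihood(gene, "no_shift", referenceGroup,
                                control = control,
                                extraStarts = list(hypStart(sf)[1:3]))
      if (is.finite(ns2@logLik) && ns2@logLik > ns@logLik + 1e-9) {
        fits[["no_shift"]] <- ns2
        logLik["no_shift"] <- ns2@logLik
        ord <- match(gene@groups[gene@groups != referenceGroup],
                     names(sf@shifts))
        sf <- maximizeLikelihood(gene, "shift", referenceGroup,
                                 control = control,
                                 extraStarts = list(
                                   hypStart(sf, unname(sf@shifts[ord])),
                                   hypStart(ns2)))
      }
    }
    fits[["shift"]] <- sf
    logLik["shift"] <- sf@logLik
  }

  shifts <- if (!is.null(fits[["shift"]])) fits[["shift"]]@shifts else
    setNames(rep(NA_real_, length(gene@groups)), gene@groups)
  new("GeneResult", geneId = gene@geneId, logLik = logLik,
      llrShape = unname(logLik["shift"] - logLik["independence"]),
      llrShift = unname(logLik["shift"] - logLik["no_shift"]),
      shifts = shifts, fits = fits, label = "unclassified")
}

## Extract one gene's GeneSeries from matrix rows + metadata; drops samples
## with missing expression. Returns NULL (skip) if any group keeps < minPts.
.geneFromRow <- function(geneId, y, times, group, minPts = 3L) {
  keep <- is.finite(y) & is.finite(times)
  y <- y[keep]; times <- times[keep]; group <- group[keep]
  levels <- unique(group)
  tl <- split(times, factor(group, levels = levels))
  yl <- split(y, factor(group, levels = levels))
  if (length(tl) < 2L || any(vapply(tl, length, 0L) < minPts))
    return(NULL)
  GeneSeries(geneId, times = tl, expr = yl)
}

#' Fit temporal-shift models to every gene of an expression table
#'
#' Applies \code{\link{fitGene}} to each row of a genes x samples expression
#' matrix. Samples carry a group label and a continuous time coordinate;
#' groups may have unequal sizes and unmatched time points. Samples with
#' missing expression are dropped per gene; a gene is skipped (reported
#' \code{unclassified} with \code{NA} likelihoods) when any group retains
#' fewer than 3 observations. Genes are independent units of work and the
#' fit is deterministic, so results do not depend on processing order.
#'
#' @param x a \code{SummarizedExperiment} (first assay = log-scale
#'   expression, \code{colData} columns \code{group} and \code{time}; an
#'   optional assay named \code{"time"} supplies per-gene observation
#'   times), or a numeric matrix.
#' @param metadata for the matrix method: a \code{data.frame} with columns
#'   \code{sample}, \code{group}, \code{time} covering every column of
#'   \code{x}.
#' @param referenceGroup reference group label; default: first group in
#'   metadata order.
#' @param models subset of models to fit (all three by default).
#' @param control settings from \code{\link{tsControl}}.
#' @param verbose print a progress line every 50 genes.
#' @return a \code{\link{TempShiftResults}}.
#' @export
setGeneric("fitTempShift", function(x, ...) standardGeneric("fitTempShift"))

#' @rdname fitTempShift
#' @param ... passed between methods.
#' @export
setMethod("fitTempShift", "SummarizedExperiment",
  function(x, referenceGroup = NULL, models = .MODEL_KINDS,
           control = tsControl(), verbose = FALSE) {
    cd <- colData(x)
    if (!all(c("group", "time") %in% colnames(cd)))
      stop("colData must contain 'group' and 'time' columns")
    timeAssay <- if ("time" %in% assayNames(x)) assay(x, "time") else NULL
    .fitTable(as.matrix(assay(x, 1L)), as.character(cd$group),
              as.numeric(cd$time), timeAssay, referenceGroup, models,
              control, verbose)
  })

#' @rdname fitTempShift
#' @export
setMethod("fitTempShift", "matrix",
  function(x, metadata, referenceGroup = NULL, models = .MODEL_KINDS,
           control = tsControl(), verbose = FALSE) {
    .checkMetadata(x, metadata)
    m <- metadata[match(colnames(x), metadata$sample), ]
    .fitTable(x, as.character(m$group), as.numeric(m$time), NULL,
              referenceGroup, models, control, verbose)
  })

.checkMetadata <- function(x, metadata) {
  need <- c("sample", "group", "time")
  if (!all(need %in% colnames(metadata)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  orphan <- setdiff(colnames(x), metadata$sample)
  if (length(orphan))
    stop("expression columns missing from metadata: ",
         paste(orphan, collapse = ", "))
  if (anyDuplicated(metadata$sample))
    stop("duplicated sample identifiers in metadata: ",
         paste(unique(metadata$sample[duplicated(metadata$sample)]),
               collapse = ", "))
  if (!all(is.finite(metadata$time)))
    stop("non-finite times in metadata")
  invisible(TRUE)
}

.fitTable <- function(expr, group, time, timeAssay, referenceGroup,
                      models, control, verbose) {
  groups <- unique(group)
  if (is.null(referenceGroup)) referenceGroup <- groups[1L]
  if (!referenceGroup %in% groups)
    stop("reference group '", referenceGroup, "' not found")
  nG <- nrow(expr)
  geneIds <- rownames(expr)
  if (is.null(geneIds))
    geneIds <- sprintf("gene%d", seq_len(nG))

  dtCols <- paste0("dt_", groups)
  na <- rep(NA_real_, nG)
  out <- data.frame(gene_id = geneIds,
                    logLik_independence = na,
                    logLik_no_shift = na, logLik_shift = na,
                    llrShape = na, llrShift = na,
                    stringsAsFactors = FALSE)
  for (cc in dtCols) out[[cc]] <- na
  out$sigmaF <- na; out$lengthScale <- na
  out$noiseSD <- na
  out$converged <- rep(NA, nG)
  out$label <- rep("unclassified", nG)

  nFail <- 0L; nSkip <- 0L
  for (i in seq_len(nG)) {
    ti <- if (is.null(timeAssay)) time else as.numeric(timeAssay[i, ])
    gs <- .geneFromRow(geneIds[i], as.numeric(expr[i, ]), ti, group)
    if (is.null(gs)) { nSkip <- nSkip + 1L; next }
    r <- fitGene(gs, referenceGroup, models, control)
    out$logLik_independence[i] <- r@logLik["independence"]
    out$logLik_no_shift[i] <- r@logLik["no_shift"]
    out$logLik_shift[i] <- r@logLik["shift"]
    out$llrShape[i] <- r@llrShape
    out$llrShift[i] <- r@llrShift
    for (gname in gs@groups)
      out[[paste0("dt_", gname)]][i] <- r@shifts[gname]
    sf <- r@fits[["shift"]]
    if (!is.null(sf)) {
      out$sigmaF[i] <- sf@params@sigmaF
      out$lengthScale[i] <- sf@params@lengthScale
      out$noiseSD[i] <- sf@params@noiseSD
    }
    conv <- vapply(r@fits, slot, TRUE, "converged")
    out$converged[i] <- all(conv)
    if (!all(conv)) nFail <- nFail + 1L
    if (verbose && i %% 50L == 0L)
      message("fitted ", i, "/", nG, " genes")
  }
  if (nSkip) message(nSkip, " gene(s) skipped (too few observations)")
  if (nFail) message(nFail, " gene(s) with non-converged model fits")

  new("TempShiftResults", results = DataFrame(out),
      referenceGroup = referenceGroup, groups = groups,
      metadata = list(models = models, control = control,
                      version = as.character(packageVersion("tempshift"))))
}
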