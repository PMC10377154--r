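#' Read a gene-by-sample expression table
#'
#' Tab-separated, UTF-8, header row of sample identifiers, first column
#' \code{gene_id}, \code{NA} as the missing marker -- the conventional
#' series-matrix-style layout. Values are log-scale expression.
#'
#' @param path file path.
#' @return numeric matrix with gene ids as row names.
#' @export
readExpression <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(tab)[1L] != "gene_id")
    stop("first column must be named 'gene_id'")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated gene identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicated sample identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (!is.numeric(m)) {
    bad <- colnames(m)[!vapply(seq_len(ncol(m)),
                               function(j) is.numeric(tab[[j + 1L]]), TRUE)]
    stop("non-numeric expression values in column(s): ",
         paste(bad, collapse = ", "))
  }
  rownames(m) <- ids
  m
}

#' Read a sample metadata table
#'
#' Tab-separated with columns \code{sample}, \code{group} and \code{time}
#' (or \code{days} together with \code{log2Days = TRUE}, in which case the
#' analysis time coordinate is \code{log2(days)}).
#'
#' @param path file path.
#' @param log2Days read a \code{days} column and log2-transform it.
#' @return \code{data.frame} with columns \code{sample}, \code{group},
#'   \code{time}.
#' @export
readMetadata <- function(path, log2Days = FALSE) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  timeCol <- if (log2Days) "days" else "time"
  need <- c("sample", "group", timeCol)
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample))
    stop("duplicated sample identifiers: ",
         paste(unique(tab$sample[duplicated(tab$sample)]), collapse = ", "))
  time <- as.numeric(tab[[timeCol]])
  if (log2Days) {
    if (any(!is.finite(time)) || any(time <= 0))
      stop("'days' must be positive and finite for log2 transformation")
    time <- log2(time)
  }
  if (any(!is.finite(time))) stop("non-finite times in metadata")
  data.frame(sample = as.character(tab$sample),
             group = as.character(tab$group), time = time,
             stringsAsFactors = FALSE)
}

#' Assemble expression and metadata into a SummarizedExperiment
#'
#' Cross-checks the two tables (every expression column must appear exactly
#' once in the metadata) and returns the container used by
#' \code{\link{fitTempShift}} and \code{\link{filterDynamicGenes}}.
#'
#' @param expr numeric genes x samples matrix.
#' @param metadata \code{data.frame} with columns \code{sample},
#'   \code{group}, \code{time}.
#' @return a \code{SummarizedExperiment}.
#' @export
makeTimecourseExperiment <- function(expr, metadata) {
  .checkMetadata(expr, metadata)
  m <- metadata[match(colnames(expr), metadata$sample), ]
  SummarizedExperiment(assays = list(expr = expr),
                       colData = DataFrame(m, row.names = m$sample))
}

#' Write / read a results table
#'
#' Tab-separated results with one row per gene and a commented header
#' (\code{# key: value} lines) recording the run metadata needed to
#' reproduce the run (reference group, thresholds, seed, version). Numbers
#' are written with 9 significant digits.
#'
#' @param x a \code{\link{TempShiftResults}}.
#' @param path output file path.
#' @return \code{writeResultsTable} returns \code{path} invisibly;
#'   \code{readResultsTable} returns a \code{data.frame} with the header
#'   metadata in \code{attr(, "metadata")}.
#' @export
writeResultsTable <- function(x, path) {
  stopifnot(is(x, "TempShiftResults"))
  df <- as.data.frame(x@results)
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num))
    df[[j]] <- ifelse(is.na(df[[j]]), "NA",
                      trimws(formatC(df[[j]], digits = 9, format = "g")))
  meta <- c(referenceGroup = x@referenceGroup,
            groups = paste(x@groups, collapse = ","),
            version = x@metadata$version)
  cls <- x@metadata$classification
  if (!is.null(cls))
    meta <- c(meta, mode = cls$mode,
              shapeCut = formatC(cls$shapeCut, digits = 9, format = "g"),
              lambdaShift = formatC(cls$lambdaShift, digits = 9,
                                    format = "g"))
  if (!is.null(x@metadata$seed))
    meta <- c(meta, seed = as.character(x@metadata$seed))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^# ", lines)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", lines[h])
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]*: ", "", kv)
  }
  df <- read.delim(text = lines[-hdr], stringsAsFactors = FALSE)
  attr(df, "metadata") <- meta
  df
}

#' Run the full analysis pipeline
#'
#' Reads the expression and metadata tables, optionally pre-selects
#' temporally dynamic genes by cubic regression, fits the three models to
#' every retained gene, classifies genes with fixed or adaptive thresholds,
#' and writes the results table. Identical inputs and seed give byte
#' identical results table bodies.
#'
#' @param exprFile,metaFile input table paths (see
#'   \code{\link{readExpression}}, \code{\link{readMetadata}}).
#' @param outFile output results path.
#' @param referenceGroup reference group label; default: first in metadata
#'   order.
#' @param preselect apply the cubic-regression filter before fitting.
#' @param r2Threshold pre-selection threshold.
#' @param mode,lambdaShape,lambdaShift see \code{\link{classifyShifts}}.
#' @param log2Days metadata carries raw days; analyze log2(days).
#' @param seed integer seed recorded in the output metadata (model fitting
#'   itself is deterministic).
#' @param control settings from \code{\link{tsControl}}.
#' @param verbose progress reporting.
#' @return the labeled \code{\link{TempShiftResults}}, invisibly.
#' @export
runPipeline <- function(exprFile, metaFile, outFile, referenceGroup = NULL,
                        preselect = FALSE, r2Threshold = 0.5,
                        mode = c("fixed", "adaptive"), lambdaShape = 50,
                        lambdaShift = NULL, log2Days = FALSE, seed = 1L,
                        control = tsControl(), verbose = FALSE) {
  mode <- match.arg(mode)
  if (is.null(lambdaShift)) lambdaShift <- if (mode == "fixed") 50 else 10
  expr <- readExpression(exprFile)
  meta <- readMetadata(metaFile, log2Days = log2Days)
  .checkMetadata(expr, meta)
  set.seed(seed)
  if (preselect) {
    sel <- filterDynamicGenes(expr, meta, threshold = r2Threshold)
    expr <- expr[sel$retained, , drop = FALSE]
  }
  res <- fitTempShift(expr, meta, referenceGroup = referenceGroup,
                      control = control, verbose = verbose)
  res <- classifyShifts(res, mode = mode, lambdaShape = lambdaShape,
                        lambdaShift = lambdaShift)
  res@metadata$seed <- seed
  res@metadata$preselect <- preselect
  writeResultsTable(res, outFile)
  invisible(res)
}
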