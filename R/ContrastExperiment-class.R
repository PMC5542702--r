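.FLAG_LEVELS <- c("detected", "marginal", "absent")

#' ContrastExperiment: multi-contrast two-colour expression container
#'
#' A [SummarizedExperiment::SummarizedExperiment] specialisation holding,
#' for one probe set measured across K field-vs-reference contrasts, the
#' per-replicate log2(field/reference) ratios (`"log2ratio"` assay) and
#' the per-probe-per-array detection flags (`"flags"` assay, one of
#' `"detected"`, `"marginal"`, `"absent"`).  Columns are arrays; the
#' contrast each array belongs to is recorded in `colData(x)$contrast`,
#' the within-contrast replicate index in `colData(x)$replicate`.
#'
#' Every contrast must carry at least 2 replicate arrays and all
#' contrasts share the same probe set (the rows).
#'
#' @export
setClass("ContrastExperiment", contains = "SummarizedExperiment")

setValidity("ContrastExperiment", function(object) {
  msg <- character()
  an <- names(SummarizedExperiment::assays(object))
  if (!all(c("log2ratio", "flags") %in% an))
    msg <- c(msg, "assays 'log2ratio' and 'flags' are required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("contrast", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'contrast' and 'replicate'")
  if (length(msg) == 0L) {
    fl <- SummarizedExperiment::assay(object, "flags")
    if (!all(fl %in% .FLAG_LEVELS))
      msg <- c(msg, sprintf("detection flags must be one of %s",
                            paste(.FLAG_LEVELS, collapse = "/")))
    reps <- table(cd$contrast)
    if (length(reps) < 1L || any(reps < 2L))
      msg <- c(msg, "each contrast needs at least 2 replicate arrays")
    if (!is.numeric(SummarizedExperiment::assay(object, "log2ratio")))
      msg <- c(msg, "'log2ratio' assay must be numeric")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ContrastExperiment
#'
#' @param ratios numeric matrix, probes x arrays, of log2(field/reference)
#'   ratios.  Row names are probe identifiers (generated if absent).
#' @param contrast character/factor of length `ncol(ratios)` labelling the
#'   contrast each array belongs to.
#' @param flags character matrix of the same shape as `ratios` with values
#'   `"detected"`, `"marginal"` or `"absent"`; defaults to all detected.
#' @param rowData optional `DataFrame` of probe annotation (e.g. simulation
#'   truth labels).
#' @return A [ContrastExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(60), nrow = 5)
#' ce <- ContrastExperiment(m, contrast = rep(c("A", "B", "C"), each = 4))
#' contrastNames(ce)
#' @export
ContrastExperiment <- function(ratios, contrast, flags = NULL,
                               rowData = NULL) {
  ratios <- as.matrix(ratios)
  if (!is.numeric(ratios)) stop("'ratios' must be a numeric matrix")
  if (length(contrast) != ncol(ratios))
    stop("'contrast' must label every array (column) of 'ratios'")
  contrast <- as.character(contrast)
  if (is.null(flags)) {
    flags <- matrix("detected", nrow(ratios), ncol(ratios))
  } else {
    flags <- as.matrix(flags)
    if (!identical(dim(flags), dim(ratios)))
      stop("'flags' must have the same dimensions as 'ratios'")
  }
  if (is.null(rownames(ratios)))
    rownames(ratios) <- sprintf("probe_%05d", seq_len(nrow(ratios)))
  dimnames(flags) <- dimnames(ratios)
  replicate <- stats::ave(seq_along(contrast), contrast, FUN = seq_along)
  colnames(ratios) <- colnames(flags) <-
    paste0(contrast, "_rep", replicate)
  cd <- S4Vectors::DataFrame(contrast = contrast, replicate = replicate,
                             row.names = colnames(ratios))
  args <- list(assays = list(log2ratio = ratios, flags = flags),
               colData = cd)
  if (!is.null(rowData)) args$rowData <- rowData
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  methods::new("ContrastExperiment", se)
}

#' @describeIn ContrastExperiment labels of the contrasts, in column order.
#' @param x a `ContrastExperiment`.
#' @export
setMethod("contrastNames", "ContrastExperiment", function(x) {
  unique(as.character(SummarizedExperiment::colData(x)$contrast))
})

.contrastCols <- function(x, contrast) {
  cc <- as.character(SummarizedExperiment::colData(x)$contrast)
  if (missing(contrast) || is.null(contrast)) return(seq_along(cc))
  if (!contrast %in% cc) stop("unknown contrast: ", contrast)
  which(cc == contrast)
}

#' @describeIn ContrastExperiment log2-ratio matrix, optionally restricted
#'   to one contrast.
#' @param contrast optional single contrast label.
#' @export
setMethod("log2Ratios", "ContrastExperiment", function(x, contrast) {
  SummarizedExperiment::assay(x, "log2ratio")[, .contrastCols(x, contrast),
                                              drop = FALSE]
})

#' @describeIn ContrastExperiment detection-flag matrix, optionally
#'   restricted to one contrast.
#' @export
setMethod("detectionFlags", "ContrastExperiment", function(x, contrast) {
  SummarizedExperiment::assay(x, "flags")[, .contrastCols(x, contrast),
                                          drop = FALSE]
})

#' @describeIn ContrastExperiment simulation truth labels (`NULL` for real
#'   data): the per-probe true class and true log2 fold change.
#' @export
setMethod("truthLabels", "ContrastExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"trueClass" %in% colnames(rd)) return(NULL)
  rd[, c("trueClass", "trueLog2Fc"), drop = FALSE]
})

#' @describeIn ContrastExperiment logical vector: `TRUE` for probes whose
#'   detection flag is `"detected"` or `"marginal"` in every array of every
#'   contrast (the strict detectability filter); probes failing it are
#'   excluded from differential-expression calling.
#' @export
setMethod("detectableProbes", "ContrastExperiment", function(x) {
  fl <- SummarizedExperiment::assay(x, "flags")
  keep <- rowSums(fl == "absent") == 0L
  names(keep) <- rownames(x)
  keep
})

setMethod("show", "ContrastExperiment", function(object) {
  cn <- contrastNames(object)
  cat(sprintf("ContrastExperiment: %d probes, %d contrasts (%s)\n",
              nrow(object), length(cn), paste(cn, collapse = ", ")))
  reps <- table(SummarizedExperiment::colData(object)$contrast)
  cat("replicate arrays per contrast:",
      paste(sprintf("%s=%d", names(reps), reps), collapse = ", "), "\n")
  nd <- sum(!detectableProbes(object))
  cat(sprintf("probes failing the detectability filter: %d\n", nd))
  if (!is.null(truthLabels(object)))
    cat("simulation truth labels attached\n")
  invisible(NULL)
})
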