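#' Two-class expression matrix container
#'
#' Bundles a gene-by-sample matrix of log2 expression values with per-sample
#' class labels (cancer versus normal) and an optional batch factor. This is
#' the unit every stage of the pipeline consumes: loading, probe collapsing,
#' merging, batch adjustment, differential expression and wrapper feature
#' selection. The number of rows is the feature universe `AF` used by the
#' feature-count penalty of the selection objective.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique; all values must be finite.
#' @param labels per-sample class labels (character or factor), one per column
#'   of `values`. Exactly two distinct values are allowed once both classes
#'   are present; supervised operations require both.
#' @param batch optional per-sample batch identifiers (character or factor).
#' @param positive label value treated as the positive (cancer) class. Default
#'   `"cancer"` when present among the labels, otherwise the last level.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `labels` (factor, positive class last level), `batch`
#'   (factor or `NULL`) and `positive` (character scalar).
#' @export
expression_matrix <- function(values, labels, batch = NULL, positive = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ", paste(unique(rownames(values)[duplicated(rownames(values))])[1:3], collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ", paste(unique(colnames(values)[duplicated(colnames(values))])[1:3], collapse = ", "))
  if (!all(is.finite(values)))
    stop("'values' contains missing or non-finite entries")
  labels <- as.character(labels)
  if (length(labels) != ncol(values))
    stop("length(labels) != number of samples")
  classes <- unique(labels)
  if (length(classes) > 2) stop("more than two classes in 'labels'")
  if (is.null(positive)) {
    positive <- if ("cancer" %in% classes) "cancer" else classes[length(classes)]
  }
  if (!positive %in% classes && length(classes) == 2)
    stop("positive class '", positive, "' not found among labels")
  lev <- c(setdiff(sort(classes), positive), intersect(positive, classes))
  labels <- factor(labels, levels = lev)
  if (!is.null(batch)) {
    if (length(batch) != ncol(values)) stop("length(batch) != number of samples")
    batch <- factor(as.character(batch))
  }
  structure(list(values = values, labels = labels, batch = batch,
                 positive = positive),
            class = "ExpressionMatrix")
}

#' @exportS3Method base::print
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  cat("  classes:", paste(sprintf("%s=%d", levels(x$labels), table(x$labels)), collapse = ", "),
      sprintf("(positive = %s)\n", x$positive))
  if (!is.null(x$batch))
    cat("  batches:", paste(sprintf("%s=%d", levels(x$batch), table(x$batch)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Number of features (genes) in an ExpressionMatrix
#'
#' The feature universe size `AF` used by the selection objective.
#' @param m an `ExpressionMatrix`.
#' @return integer gene count.
#' @export
n_features <- function(m) nrow(m$values)

#' Subset an ExpressionMatrix by genes and/or samples
#'
#' @param m an `ExpressionMatrix`.
#' @param genes gene index/name/logical vector (default all).
#' @param samples sample index/name/logical vector (default all).
#' @return the subset `ExpressionMatrix`.
#' @export
em_subset <- function(m, genes = NULL, samples = NULL) {
  v <- m$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  keep <- if (is.null(samples)) seq_len(ncol(v)) else samples
  v <- v[, keep, drop = FALSE]
  lab <- as.character(m$labels)[if (is.character(keep)) match(keep, colnames(m$values)) else keep]
  bat <- if (is.null(m$batch)) NULL else
    as.character(m$batch)[if (is.character(keep)) match(keep, colnames(m$values)) else keep]
  expression_matrix(v, lab, batch = bat, positive = m$positive)
}

# binary 0/1 vector of labels, 1 = positive (cancer) class
label01 <- function(m) as.integer(m$labels == m$positive)
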