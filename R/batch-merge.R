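#' Merge expression matrices on their common genes
#'
#' Column-binds two or more studies after restricting every matrix to the
#' intersection of their gene sets (sorted lexicographically). Each input
#' becomes one batch level in the merged object, so the result is ready for
#' [combat_adjust()].
#'
#' @param ms list of `ExpressionMatrix` objects (at least two).
#' @param batch_ids optional character names for the batches; defaults to
#'   `"b1"`, `"b2"`, ...
#' @return merged `ExpressionMatrix` with a batch factor.
#' @export
merge_expression <- function(ms, batch_ids = NULL) {
  if (!is.list(ms) || length(ms) < 2) stop("need a list of >= 2 matrices")
  stopifnot(all(vapply(ms, inherits, logical(1), "ExpressionMatrix")))
  common <- Reduce(intersect, lapply(ms, function(m) rownames(m$values)))
  if (length(common) == 0) stop("empty gene intersection across inputs")
  common <- sort(common)
  ids <- unlist(lapply(ms, function(m) colnames(m$values)))
  if (anyDuplicated(ids))
    stop("sample id collision across inputs: ", ids[duplicated(ids)][1])
  if (is.null(batch_ids)) batch_ids <- paste0("b", seq_along(ms))
  values <- do.call(cbind, lapply(ms, function(m) m$values[common, , drop = FALSE]))
  labels <- unlist(lapply(ms, function(m) as.character(m$labels)))
  batch <- rep(batch_ids, vapply(ms, function(m) ncol(m$values), integer(1)))
  expression_matrix(values, labels, batch = batch, positive = ms[[1]]$positive)
}

#' Empirical-Bayes batch adjustment (ComBat)
#'
#' Removes additive and multiplicative batch effects from a merged matrix
#' using the parametric empirical-Bayes location/scale model of ComBat
#' (`sva::ComBat`). Class labels are included as a covariate in the
#' standardization design by default so that biological signal is not
#' absorbed into the batch estimates. A single-batch input is returned
#' unchanged (nothing to adjust).
#'
#' @param m an `ExpressionMatrix` with a batch factor.
#' @param use_labels include the class labels as a model covariate
#'   (default `TRUE`).
#' @return the adjusted `ExpressionMatrix`; attribute `"adjustment"` carries
#'   an audit list with batch sizes and per-(batch, gene) location summaries
#'   before and after adjustment.
#' @export
combat_adjust <- function(m, use_labels = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(m$batch)) stop("no batch labels on input")
  sizes <- table(m$batch)
  if (length(sizes) < 2) {
    message("combat_adjust: single batch, returning input unchanged")
    return(m)
  }
  if (any(sizes < 2))
    stop("batch with fewer than 2 samples: ", names(sizes)[sizes < 2][1])
  mod <- if (use_labels && nlevels(droplevels(m$labels)) == 2)
    stats::model.matrix(~labels, data = data.frame(labels = m$labels)) else NULL
  adj <- suppressMessages(
    sva::ComBat(dat = m$values, batch = m$batch, mod = mod,
                par.prior = TRUE, prior.plots = FALSE)
  )
  if (!all(is.finite(adj))) stop("adjustment produced non-finite values")
  out <- expression_matrix(adj, as.character(m$labels),
                           batch = as.character(m$batch), positive = m$positive)
  gap <- function(v) {
    mu <- vapply(levels(m$batch), function(b) rowMeans(v[, m$batch == b, drop = FALSE]),
                 numeric(nrow(v)))
    mu
  }
  attr(out, "adjustment") <- list(
    batch_sizes = as.integer(sizes),
    batch_levels = names(sizes),
    batch_gene_means_before = gap(m$values),
    batch_gene_means_after = gap(adj))
  out
}

#' Principal-component scores of the samples
#'
#' Centers the samples-by-genes data and returns scores on the top `k`
#' principal components together with the fraction of variance each explains.
#' Used as the diagnostic for batch-effect removal: before adjustment,
#' samples separate by study along PC1; afterwards they should not.
#'
#' @param m an `ExpressionMatrix`.
#' @param k number of components (default 2).
#' @return a `PCAResult` list: `scores` (samples x k), `var_explained`
#'   (length-k fractions, non-increasing), `labels`, `batch`.
#' @export
pca_scores <- function(m, k = 2) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (k > ncol(m$values)) stop("k exceeds the number of samples")
  p <- stats::prcomp(t(m$values), center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x[, seq_len(k), drop = FALSE],
                 var_explained = ve[seq_len(k)],
                 labels = m$labels, batch = m$batch),
            class = "PCAResult")
}

#' Point-biserial correlation between a PC and a two-level grouping
#'
#' @param pca a [pca_scores()] result.
#' @param group two-level factor over the samples (e.g. the batch).
#' @param component which component to use (default 1).
#' @return the Pearson correlation between the scores and the 0/1 group
#'   indicator.
#' @export
pc_group_correlation <- function(pca, group, component = 1) {
  g <- as.integer(factor(group)) - 1L
  if (length(unique(g)) != 2) stop("'group' must have exactly two levels")
  stats::cor(pca$scores[, component], g)
}
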