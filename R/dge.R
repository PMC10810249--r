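#' Differential-expression configuration
#'
#' @param lfc_threshold minimum absolute log2 fold change for a gene to be
#'   called differentially expressed (default 2).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param test `"welch_t"` (two-sample Welch t statistic per gene) or
#'   `"moderated_t"` (limma's empirical-Bayes moderated t).
#' @return a `DGEConfig` list.
#' @export
dge_config <- function(lfc_threshold = 2, alpha = 0.05,
                       test = c("welch_t", "moderated_t")) {
  stopifnot(lfc_threshold > 0, alpha > 0, alpha < 1)
  structure(list(lfc_threshold = lfc_threshold, alpha = alpha,
                 test = match.arg(test)), class = "DGEConfig")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector, with input
#' validation. Thin wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# vectorized per-row Welch t-test: x (genes x n1) vs y (genes x n2)
row_welch <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  # constant rows have zero pooled variance; define t = 0, p = 1
  degen <- se2 <= 0 | !is.finite(df)
  tt[degen] <- 0
  df[degen] <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(tt), df)
  list(t = tt, df = df, p = p, logFC = m1 - m2)
}

#' Two-group differential expression
#'
#' Computes, for every gene, the log2 fold change (mean over cancer samples
#' minus mean over normal samples), a two-sample test statistic, its p-value
#' and the Benjamini-Hochberg adjusted p-value. A gene is flagged as a DEG
#' when `|logFC| > lfc_threshold` and `adj_p < alpha`.
#'
#' @param m an `ExpressionMatrix` with both classes present (>= 2 samples
#'   each).
#' @param cfg a [dge_config()].
#' @return a data frame with one row per gene: `gene`, `logFC`, `t`, `p`,
#'   `adj_p`, `direction` (`"up"`/`"down"`), `deg` (logical). Attribute
#'   `"counts"` holds the DEG / up / down tallies.
#' @export
compute_dge <- function(m, cfg = dge_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(cfg, "DGEConfig"))
  pos <- m$labels == m$positive
  if (sum(pos) < 2 || sum(!pos) < 2)
    stop("each class needs at least 2 samples")
  if (cfg$test == "welch_t") {
    w <- row_welch(m$values[, pos, drop = FALSE], m$values[, !pos, drop = FALSE])
    logFC <- w$logFC; tstat <- w$t; p <- w$p
  } else {
    design <- stats::model.matrix(~label01(m))
    fit <- limma::eBayes(limma::lmFit(m$values, design))
    logFC <- fit$coefficients[, 2]
    tstat <- fit$t[, 2]
    p <- fit$p.value[, 2]
  }
  adj <- bh_adjust(p)
  res <- data.frame(gene = rownames(m$values), logFC = logFC, t = tstat,
                    p = p, adj_p = adj,
                    direction = ifelse(logFC > 0, "up", "down"),
                    deg = abs(logFC) > cfg$lfc_threshold & adj < cfg$alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "counts") <- c(total = nrow(res), deg = sum(res$deg),
                           up = sum(res$deg & res$direction == "up"),
                           down = sum(res$deg & res$direction == "down"))
  res
}

#' Genes called differentially expressed
#'
#' @param dge result of [compute_dge()].
#' @return character vector of DEG gene ids.
#' @export
deg_genes <- function(dge) dge$gene[dge$deg]
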