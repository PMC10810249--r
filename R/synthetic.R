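#' Specification of a synthetic two-class expression dataset
#'
#' Emulates RMA-scale (log2, approximately Gaussian per gene) two-class
#' expression data with a small planted set of informative genes: each
#' informative gene's mean shifts by `effect_size` log2 units in the cancer
#' class, with a random sign per gene so both up- and down-regulated genes
#' occur. Class imbalance defaults to 4:1 cancer:normal, mirroring typical
#' case-control expression cohorts. An optional batch block adds per-gene
#' additive shifts and noise-scale factors to the second batch.
#'
#' @param n_samples total samples (default 160).
#' @param n_genes total genes (default 500).
#' @param n_informative planted informative genes (default 30).
#' @param effect_size mean absolute log2 shift of informative genes
#'   (default 2.5).
#' @param noise_sd per-gene Gaussian noise standard deviation (default 0.5).
#' @param baseline mean log2 expression level (default 7.0).
#' @param imbalance positive-class (cancer) fraction (default 0.8).
#' @param batch optional list: `n_batches` (must be 2 for
#'   [generate_batched_pair()]), `shift_sd` (sd of the per-gene additive
#'   batch shift), `scale_sd` (sd of the per-gene log noise-scale factor).
#' @param seed integer seed.
#' @return a `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_samples = 160, n_genes = 500, n_informative = 30,
                           effect_size = 2.5, noise_sd = 0.5, baseline = 7.0,
                           imbalance = 0.8, batch = NULL, seed = 1) {
  stopifnot(n_informative <= n_genes, imbalance > 0, imbalance < 1,
            noise_sd > 0, n_samples >= 4)
  if (!is.null(batch)) {
    batch <- utils::modifyList(list(n_batches = 2, shift_sd = 1.0, scale_sd = 0),
                               batch)
  }
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_informative = n_informative, effect_size = effect_size,
                 noise_sd = noise_sd, baseline = baseline,
                 imbalance = imbalance, batch = batch, seed = seed),
            class = "SyntheticSpec")
}

# deterministic label vector at the spec's imbalance, then shuffled
.synth_labels <- function(n, imbalance) {
  n_pos <- round(n * imbalance)
  if (n_pos < 2 || n - n_pos < 2) stop("imbalance leaves a class with <2 samples")
  sample(c(rep("cancer", n_pos), rep("normal", n - n_pos)))
}

# core generator; assumes RNG state is already set by the caller
.synth_core <- function(spec, sample_prefix = "s", shift = NULL, scale = NULL) {
  g <- spec$n_genes; n <- spec$n_samples
  labels <- .synth_labels(n, spec$imbalance)
  informative <- sort(sample.int(g, spec$n_informative))
  sign <- sample(c(-1, 1), spec$n_informative, replace = TRUE)
  mu <- matrix(spec$baseline, g, n)
  pos <- labels == "cancer"
  mu[informative, pos] <- mu[informative, pos] + sign * spec$effect_size
  noise <- matrix(stats::rnorm(g * n, sd = spec$noise_sd), g, n)
  if (!is.null(scale)) noise <- noise * scale
  values <- mu + noise
  if (!is.null(shift)) values <- values + shift
  rownames(values) <- sprintf("gene%04d", seq_len(g))
  colnames(values) <- paste0(sample_prefix, seq_len(n))
  list(values = values, labels = labels,
       informative = rownames(values)[informative], sign = sign)
}

#' Generate a synthetic two-class expression dataset
#'
#' @param spec a [synthetic_spec()].
#' @return list with `matrix` (an `ExpressionMatrix`) and `informative`
#'   (character ids of the planted genes; attribute `"sign"` gives each
#'   gene's shift direction).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  out <- with_preserved_rng(spec$seed, .synth_core(spec))
  inf <- out$informative
  attr(inf, "sign") <- out$sign
  list(matrix = expression_matrix(out$values, out$labels, positive = "cancer"),
       informative = inf)
}

#' Generate a pair of batches with shared biology and distinct batch effects
#'
#' Both matrices share the gene universe and the planted informative set
#' (identical biological signal); the second batch additionally receives a
#' per-gene additive shift `N(0, shift_sd)` and a per-gene noise scale
#' `exp(N(0, scale_sd))` as configured in the spec's `batch` block.
#'
#' @param spec a [synthetic_spec()] whose `batch` block has `n_batches = 2`.
#'   `n_samples` is the size of each batch.
#' @return list with `batches` (list of two `ExpressionMatrix`),
#'   `informative`, and `batch_shift` (the per-gene additive shifts applied
#'   to batch 2).
#' @export
generate_batched_pair <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (is.null(spec$batch)) stop("spec has no batch block")
  if (spec$batch$n_batches != 2) stop("this fixture requires exactly 2 batches")
  with_preserved_rng(spec$seed, {
    g <- spec$n_genes
    informative <- sort(sample.int(g, spec$n_informative))
    sign <- sample(c(-1, 1), spec$n_informative, replace = TRUE)
    shift <- stats::rnorm(g, sd = spec$batch$shift_sd)
    scale <- if (spec$batch$scale_sd > 0)
      exp(stats::rnorm(g, sd = spec$batch$scale_sd)) else NULL
    make <- function(prefix, shift_g, scale_g) {
      labels <- .synth_labels(spec$n_samples, spec$imbalance)
      mu <- matrix(spec$baseline, g, spec$n_samples)
      pos <- labels == "cancer"
      mu[informative, pos] <- mu[informative, pos] + sign * spec$effect_size
      noise <- matrix(stats::rnorm(g * spec$n_samples, sd = spec$noise_sd),
                      g, spec$n_samples)
      if (!is.null(scale_g)) noise <- noise * scale_g
      values <- mu + noise
      if (!is.null(shift_g)) values <- values + shift_g
      rownames(values) <- sprintf("gene%04d", seq_len(g))
      colnames(values) <- paste0(prefix, seq_len(spec$n_samples))
      expression_matrix(values, labels, positive = "cancer")
    }
    b1 <- make("a", NULL, NULL)
    b2 <- make("b", shift, scale)
    list(batches = list(b1, b2),
         informative = sprintf("gene%04d", informative),
         batch_shift = shift)
  })
}
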