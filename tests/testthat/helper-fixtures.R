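# small in-code fixtures shared across the suite

tiny_em <- function(values = NULL, labels = c("cancer", "cancer", "normal", "normal")) {
  if (is.null(values)) {
    values <- matrix(c(4, 6, 8, 2,
                       5, 5, 5, 7,
                       1, 2, 3, 4), nrow = 3, byrow = TRUE)
  }
  rownames(values) <- paste0("g", seq_len(nrow(values)))
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  expression_matrix(values, labels)
}

# quick synthetic split used by objective/pipeline tests
small_split <- function(seed = 5, n_samples = 60, n_genes = 40, n_informative = 6) {
  d <- generate_dataset(synthetic_spec(n_samples = n_samples, n_genes = n_genes,
                                       n_informative = n_informative, seed = seed))
  list(split = stratified_split(d$matrix, seed = seed), truth = d$informative,
       matrix = d$matrix)
}
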