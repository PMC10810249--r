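test_that("merge_expression intersects genes and concatenates samples", {
  v1 <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("x1", "x2")))
  v2 <- matrix(7:12, 3, 2, dimnames = list(c("B", "C", "D"), c("y1", "y2")))
  m1 <- expression_matrix(v1, c("cancer", "normal"))
  m2 <- expression_matrix(v2, c("cancer", "normal"))
  mg <- merge_expression(list(m1, m2))
  expect_identical(rownames(mg$values), c("B", "C"))
  expect_identical(colnames(mg$values), c("x1", "x2", "y1", "y2"))
  expect_identical(as.character(mg$batch), c("b1", "b1", "b2", "b2"))

  # self-merge with renamed samples doubles the columns, same genes
  v2b <- v1; colnames(v2b) <- c("z1", "z2")
  mg2 <- merge_expression(list(m1, expression_matrix(v2b, c("cancer", "normal"))))
  expect_identical(dim(mg2$values), c(3L, 4L))

  v3 <- matrix(1:4, 2, 2, dimnames = list(c("E", "F"), c("w1", "w2")))
  expect_error(merge_expression(list(m1, expression_matrix(v3, c("cancer", "normal")))),
               "empty gene intersection")
  expect_error(merge_expression(list(m1, m1)), "collision")
})

test_that("ComBat adjustment removes planted batch shifts", {
  spec <- synthetic_spec(n_samples = 40, n_genes = 300, n_informative = 20,
                         batch = list(n_batches = 2, shift_sd = 1.0), seed = 21)
  pr <- generate_batched_pair(spec)
  mg <- merge_expression(pr$batches)
  gap <- function(m) mean(abs(rowMeans(m$values[, m$batch == "b1"]) -
                              rowMeans(m$values[, m$batch == "b2"])))
  # construction: per-gene gaps are N(shift_g, noise), sd of gaps ~ shift_sd
  gaps_pre <- rowMeans(mg$values[, mg$batch == "b1"]) -
              rowMeans(mg$values[, mg$batch == "b2"])
  expect_gt(sd(gaps_pre), 0.7)
  adj <- combat_adjust(mg)
  expect_identical(dim(adj$values), dim(mg$values))
  expect_identical(rownames(adj$values), rownames(mg$values))
  expect_true(all(is.finite(adj$values)))
  expect_lt(gap(adj), 0.05)

  # near-idempotence: a second pass changes values far less than the first
  adj2 <- combat_adjust(adj)
  d1 <- median(abs(adj$values - mg$values))
  d2 <- median(abs(adj2$values - adj$values))
  expect_lt(d2, 0.05 * d1)
  expect_lt(d2, 0.01)

  # audit attachment
  aud <- attr(adj, "adjustment")
  expect_identical(aud$batch_sizes, c(40L, 40L))
  expect_identical(dim(aud$batch_gene_means_after), c(300L, 2L))
})

test_that("adjustment on null data changes values by less than noise/2", {
  spec <- synthetic_spec(n_samples = 40, n_genes = 300, n_informative = 20,
                         noise_sd = 0.5,
                         batch = list(n_batches = 2, shift_sd = 0), seed = 22)
  pr <- generate_batched_pair(spec)
  mg <- merge_expression(pr$batches)
  adj <- combat_adjust(mg)
  expect_lt(median(abs(adj$values - mg$values)), 0.25)
})

test_that("single-batch input passes through combat unchanged", {
  m <- tiny_em()
  m$batch <- factor(rep("b1", 4))
  out <- suppressMessages(combat_adjust(m))
  expect_equal(out$values, m$values)
  m2 <- tiny_em()
  m2$batch <- factor(c("b1", "b1", "b1", "b2"))
  expect_error(combat_adjust(m2), "fewer than 2")
})

test_that("pca_scores reports sane variance fractions and separation", {
  # all variance on one axis
  v <- rbind(g1 = c(0, 2, 4, 6), g2 = c(5, 5, 5, 5) + 1e-9 * (1:4))
  colnames(v) <- paste0("s", 1:4)
  m <- expression_matrix(v, c("cancer", "cancer", "normal", "normal"))
  p <- pca_scores(m)
  expect_equal(p$var_explained[1], 1.0, tolerance = 1e-6)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_error(pca_scores(m, k = 10), "exceeds")

  # duplicated samples get identical scores
  v2 <- v[, c(1, 1, 2, 3)]; colnames(v2) <- paste0("t", 1:4)
  p2 <- pca_scores(expression_matrix(v2, c("cancer", "cancer", "normal", "normal")))
  expect_equal(p2$scores[1, ], p2$scores[2, ])

  # batch separation collapses after adjustment
  spec <- synthetic_spec(n_samples = 40, n_genes = 300, n_informative = 20,
                         batch = list(n_batches = 2, shift_sd = 1.0), seed = 23)
  pr <- generate_batched_pair(spec)
  mg <- merge_expression(pr$batches)
  expect_gt(abs(pc_group_correlation(pca_scores(mg), mg$batch)), 0.8)
  adj <- combat_adjust(mg)
  expect_lt(abs(pc_group_correlation(pca_scores(adj), adj$batch)), 0.3)
})
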