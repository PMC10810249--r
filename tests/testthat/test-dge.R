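bh_brute <- function(p) {
  # direct step-up definition: adj_(i) = min over j >= i of min(1, n/j * p_(j))
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, n / seq_len(n) * ps)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- adj
  out
}

test_that("bh_adjust matches the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(31)
  for (i in 1:500) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), bh_brute(p))
  }
})

test_that("row-wise Welch t agrees with stats::t.test", {
  set.seed(32)
  v <- matrix(rnorm(20 * 12, 7), 20, 12)
  rownames(v) <- paste0("g", 1:20); colnames(v) <- paste0("s", 1:12)
  lab <- rep(c("cancer", "normal"), each = 6)
  m <- expression_matrix(v, lab)
  res <- compute_dge(m, dge_config())
  for (i in c(1, 7, 20)) {
    tt <- t.test(v[i, lab == "cancer"], v[i, lab == "normal"])
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(res$logFC[i],
                 mean(v[i, lab == "cancer"]) - mean(v[i, lab == "normal"]))
  }
  expect_true(all(res$adj_p >= res$p))
  expect_identical(res$direction, ifelse(res$logFC > 0, "up", "down"))
})

test_that("planted shifts are recovered and flat genes are not called", {
  set.seed(33)
  n1 <- 20; n2 <- 20
  v <- matrix(rnorm(50 * (n1 + n2), 7, 0.3), 50, n1 + n2)
  v[1, 1:n1] <- v[1, 1:n1] + 3  # planted +3 shift in the cancer group
  rownames(v) <- paste0("g", 1:50); colnames(v) <- paste0("s", 1:(n1 + n2))
  m <- expression_matrix(v, rep(c("cancer", "normal"), c(n1, n2)))
  res <- compute_dge(m, dge_config())
  expect_true(res$deg[1])
  expect_identical(res$direction[1], "up")
  expect_lt(abs(res$logFC[1] - 3), 0.3)

  # identical group means: logFC exactly 0, never a DEG
  v2 <- v; v2[2, ] <- rep(c(1, 2, 5), length.out = n1 + n2)
  v2[2, (n1 + 1):(n1 + n2)] <- v2[2, 1:n2]
  m2 <- expression_matrix(v2, rep(c("cancer", "normal"), c(n1, n2)))
  res2 <- compute_dge(m2, dge_config())
  expect_equal(res2$logFC[2], 0)
  expect_false(res2$deg[2])

  expect_error(compute_dge(em_subset(m, samples = c(1, 21, 22, 23))),
               "at least 2")
})

test_that("moderated-t option shrinks toward similar calls on strong effects", {
  set.seed(34)
  v <- matrix(rnorm(100 * 20, 7, 0.4), 100, 20)
  v[1:3, 1:10] <- v[1:3, 1:10] + 3
  rownames(v) <- paste0("g", 1:100); colnames(v) <- paste0("s", 1:20)
  m <- expression_matrix(v, rep(c("cancer", "normal"), each = 10))
  res <- compute_dge(m, dge_config(test = "moderated_t"))
  expect_true(all(res$deg[1:3]))
  expect_lt(sum(res$deg[4:100]), 3)
})

test_that("null simulation keeps false discoveries controlled", {
  # 1000 null genes x 50 replicates: the adjusted-p rule alone rejects in at
  # most ~alpha of replicates, and the joint DEG rule (|logFC|>2 too) nearly never
  set.seed(35)
  n_rep <- 50; n_gene <- 1000
  any_rej <- logical(n_rep); deg_count <- integer(n_rep)
  for (r in seq_len(n_rep)) {
    v <- matrix(rnorm(n_gene * 20, 7, 0.5), n_gene, 20)
    rownames(v) <- paste0("g", seq_len(n_gene)); colnames(v) <- paste0("s", 1:20)
    m <- expression_matrix(v, rep(c("cancer", "normal"), each = 10))
    res <- compute_dge(m, dge_config())
    any_rej[r] <- any(res$adj_p < 0.05)
    deg_count[r] <- sum(res$deg)
  }
  # complete null: P(any BH rejection) <= alpha; allow binomial slack
  expect_lte(mean(any_rej), 0.075 + 2 * sqrt(0.075 * 0.925 / n_rep))
  expect_lte(mean(deg_count), 0.05)
})
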