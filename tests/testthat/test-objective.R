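test_that("stratified split hits the per-class arithmetic and is seeded", {
  set.seed(51)
  v <- matrix(rnorm(5 * 100, 7), 5, 100)
  rownames(v) <- paste0("g", 1:5); colnames(v) <- paste0("s", 1:100)
  m <- expression_matrix(v, rep(c("cancer", "normal"), c(80, 20)))
  sp <- stratified_split(m, seed = 9)
  counts <- function(part) table(part$labels)
  expect_equal(unname(counts(sp$train)[c("cancer", "normal")]), c(48, 12),
               ignore_attr = TRUE)
  expect_equal(unname(counts(sp$validation)[c("cancer", "normal")]), c(16, 4),
               ignore_attr = TRUE)
  expect_equal(unname(counts(sp$test)[c("cancer", "normal")]), c(16, 4),
               ignore_attr = TRUE)
  # disjoint and exhaustive
  all_ids <- sort(unname(unlist(lapply(sp[1:3], function(p) colnames(p$values)))))
  expect_identical(all_ids, sort(colnames(v)))
  # determinism
  sp2 <- stratified_split(m, seed = 9)
  expect_identical(sp$indices, sp2$indices)
  sp3 <- stratified_split(m, seed = 10)
  expect_false(identical(sp$indices, sp3$indices))
  expect_error(stratified_split(m, fractions = c(0.6, 0.3, 0.3)), "summing to 1")
})

test_that("SMOTE balances classes with convex-combination synthetics", {
  set.seed(52)
  v <- matrix(rnorm(8 * 50, 7), 8, 50)
  rownames(v) <- paste0("g", 1:8); colnames(v) <- paste0("s", 1:50)
  m <- expression_matrix(v, rep(c("cancer", "normal"), c(40, 10)))
  out <- smote_balance(m, k = 5, seed = 3)
  expect_equal(unname(table(out$labels)[c("cancer", "normal")]), c(40, 40),
               ignore_attr = TRUE)
  # originals unchanged
  expect_equal(out$values[, colnames(v)], v, ignore_attr = TRUE)
  # every synthetic point lies on a segment between two minority originals
  minority <- v[, m$labels == "normal"]
  synth <- out$values[, grep("^smote_", colnames(out$values)), drop = FALSE]
  for (sidx in seq_len(ncol(synth))) {
    s <- synth[, sidx]
    ok <- FALSE
    for (i in seq_len(ncol(minority))) {
      for (j in seq_len(ncol(minority))) {
        if (i == j) next
        dir <- minority[, j] - minority[, i]
        if (all(abs(dir) < 1e-12)) next
        u <- (s - minority[, i]) / dir
        u <- u[is.finite(u)]
        if (length(u) && max(u) - min(u) < 1e-8 &&
            min(u) > -1e-8 && max(u) < 1 + 1e-8) { ok <- TRUE; break }
      }
      if (ok) break
    }
    expect_true(ok, label = paste("synthetic", sidx, "is a convex combination"))
  }
  # already balanced: identity
  mb <- expression_matrix(v[, 1:20], rep(c("cancer", "normal"), each = 10))
  expect_identical(smote_balance(mb, seed = 1)$values, mb$values)
  m1 <- expression_matrix(v[, c(1:5, 6)], c(rep("cancer", 5), "normal"))
  expect_error(smote_balance(m1), "fewer than 2")
})

test_that("classifier weights normalize validation metric products", {
  mk <- function(ac, pr, re, f1, f2)
    c(Ac = ac, Pr = pr, Re = re, F1 = f1, F2 = f2, MCC = 0, BAc = 0)
  same <- replicate(4, mk(0.9, 0.8, 0.7, 0.75, 0.72), simplify = FALSE)
  expect_equal(classifier_weights(same), rep(0.25, 4), ignore_attr = TRUE)

  # products (0.4, 0.4, 0.1, 0.1) -> weights proportional
  ms <- list(mk(0.4, 1, 1, 1, 1), mk(0.4, 1, 1, 1, 1),
             mk(0.1, 1, 1, 1, 1), mk(0.1, 1, 1, 1, 1))
  expect_equal(classifier_weights(ms), c(0.4, 0.4, 0.1, 0.1),
               ignore_attr = TRUE)

  ms[[2]] <- mk(0.9, 0.9, 0, 0.5, 0.5)  # zero recall -> zero weight
  w <- classifier_weights(ms)
  expect_equal(w[2], 0, ignore_attr = TRUE)
  expect_equal(sum(w), 1)

  zero <- replicate(4, mk(0, 0, 0, 0, 0), simplify = FALSE)
  wz <- classifier_weights(zero)
  expect_equal(wz, rep(0.25, 4), ignore_attr = TRUE)
  expect_true(attr(wz, "uniform_fallback"))

  set.seed(53)
  for (i in 1:200) {
    rnd <- replicate(4, mk(runif(1), runif(1), runif(1), runif(1), runif(1)),
                     simplify = FALSE)
    expect_equal(sum(classifier_weights(rnd)), 1, tolerance = 1e-12)
  }
})

test_that("weighted hard voting follows the argmax with positive ties", {
  w <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(ensemble_predict(matrix(c(1, 1, 1, 1), 1), w), 1L)
  expect_equal(ensemble_predict(matrix(c(0, 0, 0, 0), 1), w), 0L)
  # pos weight 0.4 vs neg 0.6
  expect_equal(ensemble_predict(matrix(c(1, 0, 0, 0), 1), w), 0L)
  # exact tie 0.5/0.5 -> positive
  expect_equal(ensemble_predict(matrix(c(1, 0, 0, 1), 1), w), 1L)
  expect_equal(ensemble_predict(matrix(c(1, 0, 0, 1), 1), w, tie = "negative"), 0L)
  expect_error(ensemble_predict(matrix(c(1, 0, 0), 1), w), "match")
})

test_that("fitness arithmetic, monotonicity and sentinel behave as specified", {
  expect_equal(fitness_value(1, 10629, 10629)$fit, 0.2)
  expect_equal(fitness_value(0.978, 1404, 10629)$fit, 0.0440, tolerance = 1e-3)
  expect_equal(fitness_value(0.5, 250, 500)$fit, 0.5)
  # literal published form
  expect_equal(fitness_value(0.978, 1404, 10629, form = "literal")$fit,
               0.8 * 0.978 + 0.2 * 1404 / 10629)
  # strict monotonicity in NF at fixed performance
  fits <- vapply(0:500, function(nf) fitness_value(0.9, nf, 500)$fit, numeric(1))
  expect_true(all(diff(fits) > 0))
})

test_that("fitness evaluator is deterministic, cached and split-respecting", {
  s <- small_split(seed = 54)
  f1 <- fitness_evaluator(s$split, seed = 7)
  f2 <- fitness_evaluator(s$split, seed = 7)
  set.seed(1); mask <- as.integer(runif(40) < 0.5)
  a <- f1(mask); b <- f2(mask)
  expect_equal(a$fit, b$fit)
  expect_equal(a$weights, b$weights)
  # cache: second call does not retrain
  before <- attr(f1, "stats")()$evals
  a2 <- f1(mask)
  expect_equal(attr(f1, "stats")()$evals, before)
  expect_equal(a2$fit, a$fit)
  # the oracle never sees test-partition samples
  seen <- attr(f1, "stats")()$sample_ids
  expect_length(intersect(seen, colnames(s$split$test$values)), 0)
  # empty mask: sentinel worst fitness, no training
  sent <- f1(rep(0L, 40))
  expect_equal(sent$fit, 1)
  expect_true(sent$sentinel)
  expect_equal(attr(f1, "stats")()$evals, before)
  # global RNG stream is not consumed by evaluation
  mask2 <- as.integer(runif(40) < 0.5)
  set.seed(99); before_draw <- runif(1)
  set.seed(99); invisible(f1(mask2))
  expect_equal(runif(1), before_draw)
})
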