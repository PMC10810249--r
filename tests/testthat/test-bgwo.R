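# independent scalar transcription of the binary update equations:
# A = 2 a r1 - a, C = 2 r2, D_k = |C_k X_k - X_i|, s = sigmoid(10 (A D - 0.5)),
# bstep = [s >= r3], X'_k = [X_k + bstep >= 1], crossover by thirds of r4
update_oracle <- function(wolf, leaders, a, draws) {
  d <- length(wolf)
  out <- integer(d)
  for (dim in seq_len(d)) {
    cand <- integer(3)
    for (k in 1:3) {
      A <- 2 * a * draws$r1[dim, k] - a
      C <- 2 * draws$r2[dim, k]
      D <- abs(C * leaders[[k]][dim] - wolf[dim])
      s <- 1 / (1 + exp(-10 * (A * D - 0.5)))
      bstep <- if (s >= draws$r3[dim]) 1L else 0L
      cand[k] <- if (leaders[[k]][dim] + bstep >= 1) 1L else 0L
    }
    r4 <- draws$r4[dim]
    out[dim] <- if (r4 < 1 / 3) cand[1] else if (r4 < 2 / 3) cand[2] else cand[3]
  }
  out
}

test_that("the distance-control factor is exactly linear with endpoints 2 and 0", {
  expect_equal(a_schedule(0, 100), 2.0)
  expect_equal(a_schedule(100, 100), 0.0)
  expect_equal(a_schedule(50, 100), 1.0)
  expect_equal(a_schedule(25, 100), 1.5)
  expect_error(a_schedule(101, 100), "t must lie")
})

test_that("coefficient draws respect their ranges", {
  set.seed(61)
  for (a in c(2, 1.3, 0.5, 0)) {
    dr <- wolf_update_draws(200, a)
    expect_true(all(dr$A >= -a - 1e-12 & dr$A <= a + 1e-12))
    expect_true(all(dr$C >= 0 & dr$C <= 2))
  }
})

test_that("all-ones leaders are a fixed point of the update", {
  set.seed(62)
  ones <- rep(1L, 50)
  wolf <- as.integer(runif(50) < 0.5)
  for (i in 1:10) {
    expect_identical(update_wolf_position(wolf, list(ones, ones, ones), 1.2), ones)
  }
})

test_that("vectorized update equals the scalar equation transcription bit-for-bit", {
  set.seed(63)
  for (i in 1:200) {
    d <- sample(5:40, 1)
    a <- runif(1, 0, 2)
    wolf <- as.integer(runif(d) < 0.5)
    leaders <- replicate(3, as.integer(runif(d) < 0.5), simplify = FALSE)
    draws <- wolf_update_draws(d, a)
    got <- update_wolf_position(wolf, leaders, a, draws = draws)
    expect_identical(got, update_oracle(wolf, leaders, a, draws))
    expect_true(all(got %in% c(0L, 1L)))
  }
})

test_that("crossover picks each leader branch a third of the time", {
  set.seed(64)
  # distinguishable leaders: candidate k is forced to leader k's bit by r3 = 1
  n <- 12000
  picks <- integer(3)
  d <- 1L
  l <- list(1L, 0L, 1L)
  for (i in seq_len(n)) {
    dr <- wolf_update_draws(d, 0)
    picks[1L + (dr$r4 >= 1 / 3) + (dr$r4 >= 2 / 3)] <-
      picks[1L + (dr$r4 >= 1 / 3) + (dr$r4 >= 2 / 3)] + 1L
  }
  expect_true(all(abs(picks / n - 1 / 3) < 0.02))
})

test_that("bgwo_run records a monotone elitist trace and is seed-reproducible", {
  toy <- function(mask) sum(mask) / length(mask)  # feature-count objective
  cfg <- gwo_config(n_wolves = 6, t_max = 15, seed = 5)
  r1 <- bgwo_run(toy, af = 40, cfg = cfg)
  expect_true(all(diff(r1$trace) <= 0))
  expect_length(r1$trace, 16)
  expect_lte(r1$best_fitness, r1$trace[1])
  r2 <- bgwo_run(toy, af = 40, cfg = cfg)
  expect_identical(r1$best_mask, r2$best_mask)
  expect_identical(r1$trace, r2$trace)
  r3 <- bgwo_run(toy, af = 40, cfg = gwo_config(n_wolves = 6, t_max = 15, seed = 6))
  expect_false(identical(r1$trace, r3$trace))
  expect_error(gwo_config(n_wolves = 2), "n_wolves")
})

test_that("bgwo_run improves a position-sensitive objective", {
  # reward bits on the first thirty positions, penalize the last ten
  target <- c(rep(1, 30), rep(0, 10))
  fn <- function(mask) sum(abs(mask - target)) / 40
  runs <- lapply(3:5, function(s)
    bgwo_run(fn, af = 40, cfg = gwo_config(n_wolves = 10, t_max = 25, seed = s)))
  for (r in runs) {
    expect_lte(r$best_fitness, r$trace[1])
    expect_true(all(diff(r$trace) <= 0))
  }
  expect_true(any(vapply(runs, function(r) r$best_fitness < r$trace[1],
                         logical(1))))
})
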