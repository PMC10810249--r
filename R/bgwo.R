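#' Distance-control schedule of the grey wolf optimizer
#'
#' The exploration/exploitation factor `a` starts at 2 and decreases
#' linearly to 0 over the run: `a = 2 - t * 2 / t_max`.
#'
#' @param t current iteration (0-based, `0 <= t <= t_max`).
#' @param t_max total number of iterations.
#' @return the scalar `a`.
#' @export
a_schedule <- function(t, t_max) {
  stopifnot(t_max >= 1)
  if (t < 0 || t > t_max) stop("t must lie in [0, t_max]")
  # algebraically 2 - t*(2/t_max); this form is exact at both endpoints
  2 * (1 - t / t_max)
}

#' BGWO configuration
#'
#' @param n_wolves pack size (>= 3; three leaders are required).
#' @param t_max number of iterations.
#' @param init_density Bernoulli probability of a 1 in the initial masks.
#'   The default 0.5 gives dense starting subsets; a sparse start (e.g. 0.1)
#'   is useful when the feature universe is large.
#' @param seed integer run seed.
#' @return a `GWOConfig` list.
#' @export
gwo_config <- function(n_wolves = 10, t_max = 100, init_density = 0.5, seed = 1) {
  stopifnot(n_wolves >= 3, t_max >= 1, init_density > 0, init_density < 1)
  structure(list(n_wolves = n_wolves, t_max = t_max,
                 init_density = init_density, seed = seed),
            class = "GWOConfig")
}

#' Random draws for one wolf position update
#'
#' Draws, in a fixed documented order, all random numbers one position
#' update consumes: per-dimension `r1` and `r2` for the three leader-wise
#' coefficient vectors `A_k = 2 a r1 - a` and `C_k = 2 r2`, one `r3` per
#' dimension shared by the three binary-step comparisons, and one `r4` per
#' dimension for the stochastic crossover among the three leader-derived
#' bits.
#'
#' @param d number of dimensions (features).
#' @param a current distance-control value.
#' @return a `WolfUpdateDraws` list with matrices `r1`, `r2` (`d` x 3) and
#'   vectors `r3`, `r4` (length `d`), plus the derived `A` and `C`
#'   (`d` x 3).
#' @export
wolf_update_draws <- function(d, a) {
  r1 <- matrix(stats::runif(3 * d), d, 3)
  r2 <- matrix(stats::runif(3 * d), d, 3)
  r3 <- stats::runif(d)
  r4 <- stats::runif(d)
  structure(list(r1 = r1, r2 = r2, r3 = r3, r4 = r4,
                 A = 2 * a * r1 - a, C = 2 * r2),
            class = "WolfUpdateDraws")
}

#' One binary grey-wolf position update
#'
#' Updates a wolf's 0/1 position against the three leaders. Per dimension
#' `d` and leader `k` in (alpha, beta, delta): the distance
#' `D_k = |C_k * X_k - X_i|` is squashed through the sigmoid step
#' `s_k = 1 / (1 + exp(-10 (A_k D_k - 0.5)))`, binarized by the shared draw
#' `r3` into `bstep_k`, combined with the leader bit as
#' `X'_k = 1 if X_k + bstep_k >= 1`, and the output bit is chosen among the
#' three candidates with probability 1/3 each via `r4`. Note the combination
#' rule can only add bits relative to the chosen leader, never remove them.
#'
#' @param wolf 0/1 position vector.
#' @param leaders list of three 0/1 vectors (alpha, beta, delta), same
#'   length as `wolf`.
#' @param a distance-control value in `[0, 2]`.
#' @param draws optional [wolf_update_draws()]; drawn from the current RNG
#'   stream when `NULL`.
#' @return the new 0/1 position vector.
#' @export
update_wolf_position <- function(wolf, leaders, a, draws = NULL) {
  d <- length(wolf)
  if (length(leaders) != 3 || any(lengths(leaders) != d))
    stop("need three leader masks of the same length as 'wolf'")
  if (a < 0 || a > 2) stop("'a' must lie in [0, 2]")
  if (is.null(draws)) draws <- wolf_update_draws(d, a)
  X <- matrix(0L, d, 3)
  for (k in 1:3) {
    Dk <- abs(draws$C[, k] * leaders[[k]] - wolf)
    sk <- 1 / (1 + exp(-10 * (draws$A[, k] * Dk - 0.5)))
    bstep <- as.integer(sk >= draws$r3)
    X[, k] <- as.integer(leaders[[k]] + bstep >= 1)
  }
  pick <- 1L + (draws$r4 >= 1 / 3) + (draws$r4 >= 2 / 3)
  X[cbind(seq_len(d), pick)]
}

# rank positions by fitness (minimize), ties broken by lower NF then index
leader_order <- function(fits, masks) {
  nf <- vapply(masks, sum, numeric(1))
  order(fits, nf, seq_along(fits))
}

#' Run the binary grey wolf optimizer
#'
#' Initializes `n_wolves` Bernoulli masks, then iterates: update the
#' distance-control factor, move every wolf against the current three
#' leaders, re-evaluate, re-rank. The best-so-far mask and fitness are
#' recorded each iteration (elitist trace, non-increasing). Fitness is
#' minimized; ties in leader ranking go to the mask with fewer selected
#' features, then the lower wolf index.
#'
#' @param fitness_fn function mapping a 0/1 mask to a scalar fitness or a
#'   `FitnessValue` (its `fit` element is used).
#' @param af number of features (mask length).
#' @param cfg a [gwo_config()].
#' @param refine_alpha optional function `(mask, fitness_fn) -> mask` run on
#'   the alpha wolf at the end of every iteration (used for the simulated
#'   annealing hybrid); the refined mask replaces alpha when not worse.
#' @return a `SelectionRun` list: `best_mask`, `best_fitness`, `trace`
#'   (per-iteration best-so-far fitness, length `t_max + 1` including the
#'   initial pack), `algorithm`, `seed`, `config`, `n_evaluations`.
#' @export
bgwo_run <- function(fitness_fn, af, cfg = gwo_config(), refine_alpha = NULL) {
  stopifnot(inherits(cfg, "GWOConfig"))
  fit_of <- function(f) if (inherits(f, "FitnessValue")) f$fit else as.numeric(f)
  n_eval <- 0L
  eval_fit <- function(mask) { n_eval <<- n_eval + 1L; fit_of(fitness_fn(mask)) }
  run <- function() {
    pos <- lapply(seq_len(cfg$n_wolves), function(i)
      as.integer(stats::runif(af) < cfg$init_density))
    fits <- vapply(pos, eval_fit, numeric(1))
    ord <- leader_order(fits, pos)
    best_mask <- pos[[ord[1]]]; best_fit <- fits[ord[1]]
    trace <- best_fit
    for (t in seq_len(cfg$t_max)) {
      a <- a_schedule(t, cfg$t_max)
      leaders <- pos[ord[1:3]]
      pos <- lapply(pos, update_wolf_position, leaders = leaders, a = a)
      fits <- vapply(pos, eval_fit, numeric(1))
      ord <- leader_order(fits, pos)
      if (!is.null(refine_alpha)) {
        alpha_i <- ord[1]
        refined <- refine_alpha(pos[[alpha_i]], fitness_fn)
        rf <- fit_of(fitness_fn(refined))
        if (rf <= fits[alpha_i]) {
          pos[[alpha_i]] <- refined
          fits[alpha_i] <- rf
          ord <- leader_order(fits, pos)
        }
      }
      if (fits[ord[1]] < best_fit ||
          (fits[ord[1]] == best_fit && sum(pos[[ord[1]]]) < sum(best_mask))) {
        best_fit <- fits[ord[1]]
        best_mask <- pos[[ord[1]]]
      }
      trace <- c(trace, best_fit)
    }
    list(best_mask = best_mask, best_fitness = best_fit, trace = trace)
  }
  out <- with_preserved_rng(cfg$seed, run())
  structure(c(out, list(algorithm = "bgwo", seed = cfg$seed, config = cfg,
                        n_evaluations = n_eval)),
            class = "SelectionRun")
}

#' @exportS3Method base::print
print.SelectionRun <- function(x, ...) {
  cat("SelectionRun [", x$algorithm, "] seed", x$seed, "\n")
  cat("  best fitness:", format(x$best_fitness, digits = 4),
      " selected features:", sum(x$best_mask), "/", length(x$best_mask), "\n")
  cat("  evaluations:", x$n_evaluations, " trace length:", length(x$trace), "\n")
  invisible(x)
}
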