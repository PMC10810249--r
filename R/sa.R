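#' Simulated-annealing configuration
#'
#' The cooling schedule is geometric: temperatures `T0 * cooling^k` down to
#' `t_final`, with `moves` proposals at each level. The paper-facing
#' operators all conserve the number of selected features; an optional
#' bit-flip operator (off by default) is available for schedules that should
#' also explore subset size.
#'
#' @param t0 initial temperature (default 0.1, the scale of early fitness
#'   deltas).
#' @param cooling geometric cooling factor in (0, 1) (default 0.9).
#' @param t_final final temperature (default 1e-3).
#' @param moves proposals per temperature level (default 5).
#' @param op_weights named non-negative weights over the neighborhood
#'   operators `swap`, `insertion`, `inversion`, `r2l`, `r2r` (and
#'   optionally `bitflip`); default uniform over the five.
#' @param seed optional seed; `NULL` continues the current RNG stream (the
#'   mode used inside the hybrid run).
#' @return an `SAConfig` list.
#' @export
sa_config <- function(t0 = 0.1, cooling = 0.9, t_final = 1e-3, moves = 5,
                      op_weights = NULL, seed = NULL) {
  stopifnot(t0 > 0, t_final > 0, t_final < t0, cooling > 0, cooling < 1,
            moves >= 1)
  if (is.null(op_weights))
    op_weights <- c(swap = 1, insertion = 1, inversion = 1, r2l = 1, r2r = 1)
  if (is.null(names(op_weights)) || any(op_weights < 0) || sum(op_weights) == 0)
    stop("op_weights must be named, non-negative and not all zero")
  bad <- setdiff(names(op_weights),
                 c("swap", "insertion", "inversion", "r2l", "r2r", "bitflip"))
  if (length(bad)) stop("unknown operator: ", bad[1])
  structure(list(t0 = t0, cooling = cooling, t_final = t_final, moves = moves,
                 op_weights = op_weights, seed = seed),
            class = "SAConfig")
}

#' Apply a binary neighborhood operator
#'
#' `swap` exchanges the bits at two random positions; `insertion` removes
#' the bit at one random position and reinserts it at another; `inversion`
#' reverses a random contiguous segment; `r2l` / `r2r` rotate the whole
#' vector cyclically by one position. All five conserve the number of
#' selected features. The non-default `bitflip` flips one random bit.
#'
#' @param mask 0/1 vector of length >= 2.
#' @param op operator name.
#' @return the neighboring 0/1 vector.
#' @export
apply_operator <- function(mask, op) {
  d <- length(mask)
  if (d < 2) stop("mask length must be >= 2")
  switch(op,
    swap = {
      ij <- sample.int(d, 2)
      mask[ij] <- mask[rev(ij)]
      mask
    },
    insertion = {
      ij <- sample.int(d, 2)
      i <- ij[1]; j <- ij[2]
      bit <- mask[i]
      rest <- mask[-i]
      append(rest, bit, after = j - 1)
    },
    inversion = {
      ij <- sort(sample.int(d, 2))
      mask[ij[1]:ij[2]] <- rev(mask[ij[1]:ij[2]])
      mask
    },
    r2l = c(mask[-1], mask[1]),
    r2r = c(mask[d], mask[-d]),
    bitflip = {
      i <- sample.int(d, 1)
      mask[i] <- 1L - mask[i]
      mask
    },
    stop("unknown operator: ", op)
  )
}

#' Roulette-wheel choice of a neighborhood operator
#'
#' @param weights named non-negative weights, not all zero.
#' @return one operator name, drawn with probability proportional to its
#'   weight.
#' @export
roulette_select <- function(weights) {
  if (is.null(names(weights)) || any(weights < 0) || sum(weights) == 0)
    stop("weights must be named, non-negative and not all zero")
  cum <- cumsum(weights) / sum(weights)
  names(weights)[1L + sum(stats::runif(1) > cum)]
}

#' Boltzmann acceptance rule
#'
#' A proposal no worse than the current solution (`delta_f <= 0`) is always
#' accepted; a worse one is accepted with probability `exp(-delta_f / T)`.
#'
#' @param delta_f fitness change of the proposal (positive = worse, under
#'   minimization).
#' @param temp current temperature (> 0).
#' @return logical: accept the proposal?
#' @export
boltzmann_accept <- function(delta_f, temp) {
  if (temp <= 0) stop("temperature must be positive")
  if (delta_f <= 0) return(TRUE)
  stats::runif(1) < exp(-delta_f / temp)
}

#' Simulated-annealing refinement of a feature mask
#'
#' Starting from `start` (in the hybrid, the alpha wolf), walks the
#' geometric temperature ladder; at each level it proposes `moves`
#' neighbors, each generated by a roulette-selected operator, and accepts
#' by the Boltzmann rule. The best mask ever seen is tracked and returned,
#' so the result is never worse than the start.
#'
#' @param start 0/1 mask.
#' @param fitness_fn function mapping a mask to a scalar fitness or
#'   `FitnessValue` (minimized).
#' @param cfg an [sa_config()].
#' @return the best 0/1 mask found; attributes `"fitness"` (its fitness)
#'   and `"n_proposals"`.
#' @export
sa_refine <- function(start, fitness_fn, cfg = sa_config()) {
  stopifnot(inherits(cfg, "SAConfig"))
  fit_of <- function(f) if (inherits(f, "FitnessValue")) f$fit else as.numeric(f)
  run <- function() {
    cur <- start
    cur_fit <- fit_of(fitness_fn(cur))
    best <- cur; best_fit <- cur_fit
    temp <- cfg$t0
    n_prop <- 0L
    while (temp >= cfg$t_final) {
      for (mv in seq_len(cfg$moves)) {
        op <- roulette_select(cfg$op_weights)
        cand <- apply_operator(cur, op)
        cand_fit <- fit_of(fitness_fn(cand))
        n_prop <- n_prop + 1L
        if (boltzmann_accept(cand_fit - cur_fit, temp)) {
          cur <- cand; cur_fit <- cand_fit
          if (cur_fit < best_fit) { best <- cur; best_fit <- cur_fit }
        }
      }
      temp <- temp * cfg$cooling
    }
    attr(best, "fitness") <- best_fit
    attr(best, "n_proposals") <- n_prop
    best
  }
  if (is.null(cfg$seed)) run() else with_preserved_rng(cfg$seed, run())
}
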