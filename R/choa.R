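#' Chimp Optimization Algorithm settings
#'
#' The ChoA population is steered by its four best individuals (attacker,
#' barrier, chaser, driver).  Each remaining chimp either takes the mean of
#' four leader-directed moves (with probability `prey_prob`) or performs a
#' chaotic relocation around the attacker driven by a chaotic-map value.
#'
#' @param population Population size P (default 10).
#' @param max_iter Maximum number of iterations N (default 200).
#' @param runs Number of independent repetitions r used by multi-run
#'   protocols (default 20); not consumed by a single optimization run.
#' @param prey_prob Probability threshold splitting the prey-directed move
#'   from the chaotic move (default 0.5).
#' @param l0 Initial value of the driving coefficient `l`, which decays
#'   linearly from `l0` to 0 over the iterations (default 2.5).
#' @param a_formula Either `"paper"` (a = 2*l*r1 - 1, as printed in the
#'   source method) or `"original"` (a = 2*l*r1 - l, the standard ChoA form
#'   whose attack coefficient vanishes as l -> 0 and therefore converges
#'   more tightly).
#' @param chaotic_map `"logistic"` (x <- 4x(1-x)) or `"tent"`.
#' @param map_init Initial chaotic-map state in `[0, 1]` (default 0.7).
#' @param seed Optional integer seed recorded in results.
#'
#' @return A list of class `choa_config`.
#' @export
choa_config <- function(population = 10L, max_iter = 200L, runs = 20L,
                        prey_prob = 0.5, l0 = 2.5,
                        a_formula = c("paper", "original"),
                        chaotic_map = c("logistic", "tent"),
                        map_init = 0.7, seed = NULL) {
  a_formula <- match.arg(a_formula)
  chaotic_map <- match.arg(chaotic_map)
  if (population < 2L) stop("population must be at least 2")
  if (max_iter < 1L) stop("max_iter must be at least 1")
  if (prey_prob < 0 || prey_prob > 1) stop("prey_prob must lie in [0, 1]")
  if (l0 <= 0) stop("l0 must be positive")
  if (map_init < 0 || map_init > 1) stop("map_init must lie in [0, 1]")
  structure(list(population = as.integer(population),
                 max_iter = as.integer(max_iter),
                 runs = as.integer(runs),
                 prey_prob = prey_prob, l0 = l0,
                 a_formula = a_formula, chaotic_map = chaotic_map,
                 map_init = map_init, seed = seed),
            class = "choa_config")
}

#' Linear coefficient schedule
#'
#' The driving coefficient `l` drops along a line from `l0` at iteration 0
#' to 0 at `max_iter`.
#'
#' @param iter Current iteration (0-based, `0 <= iter <= max_iter`).
#' @param max_iter Total number of iterations (>= 1).
#' @param l0 Initial coefficient value.
#' @return The scalar `l = l0 * (1 - iter / max_iter)`.
#' @examples
#' coeff_schedule(0, 200, 2.5)    # 2.5
#' coeff_schedule(200, 200, 2.5)  # 0
#' @export
coeff_schedule <- function(iter, max_iter, l0) {
  if (max_iter < 1) stop("max_iter must be at least 1")
  if (iter < 0 || iter > max_iter) {
    stop("iter must lie in [0, max_iter]")
  }
  l0 * (1 - iter / max_iter)
}

#' Advance a chaotic map
#'
#' Supplies the "disordered" coefficient m of the chimp update.  Both maps
#' send `[0, 1]` to `[0, 1]`.
#'
#' @param map_state Current state in `[0, 1]`.
#' @param map `"logistic"` (`4 x (1 - x)`) or `"tent"`
#'   (`2x` below 1/2, `2(1 - x)` above).
#' @return The next state.
#' @examples
#' chaotic_next(0.7, "logistic")  # 0.84
#' chaotic_next(0.25, "tent")     # 0.5
#' @export
chaotic_next <- function(map_state, map = c("logistic", "tent")) {
  map <- match.arg(map)
  if (!is.finite(map_state) || map_state < 0 || map_state > 1) {
    stop("map_state must lie in [0, 1]")
  }
  if (map == "logistic") {
    4 * map_state * (1 - map_state)
  } else {
    if (map_state < 0.5) 2 * map_state else 2 * (1 - map_state)
  }
}

#' ChoA update coefficients
#'
#' Computes the attack coefficient `a`, the prey-influence coefficient
#' `c_coef` in `[0, 2]`, and passes the chaotic value `m` through.
#'
#' @param l Current schedule coefficient.
#' @param r1,r2 Uniform random draws in `[0, 1]`.
#' @param m Chaotic-map value.
#' @param a_formula `"paper"` (`a = 2*l*r1 - 1`) or `"original"`
#'   (`a = 2*l*r1 - l`).
#' @return A list with elements `a`, `c_coef`, `m`.
#' @examples
#' choa_coefficients(2.5, 1, 0.5, 0.3, "paper")     # a = 4
#' choa_coefficients(2.5, 1, 0.5, 0.3, "original")  # a = 2.5
#' @export
choa_coefficients <- function(l, r1, r2, m, a_formula = c("paper", "original")) {
  a_formula <- match.arg(a_formula)
  if (r1 < 0 || r1 > 1 || r2 < 0 || r2 > 1) stop("r1 and r2 must lie in [0, 1]")
  a <- if (a_formula == "paper") 2 * l * r1 - 1 else 2 * l * r1 - l
  list(a = a, c_coef = 2 * r2, m = m)
}

#' Leader-directed candidate position
#'
#' Elementwise distance `d = |c_coef * leader - m * x|` followed by the move
#' `leader - a * d`.
#'
#' @param leader_pos Leader position vector.
#' @param x Current chimp position, same length.
#' @param a,c_coef,m Scalar coefficients (see [choa_coefficients()]).
#' @return Candidate position vector.
#' @examples
#' choa_candidate(c(2), c(1), a = 0.5, c_coef = 1, m = 1)  # 1.5
#' @export
choa_candidate <- function(leader_pos, x, a, c_coef, m) {
  if (length(leader_pos) != length(x)) {
    stop("leader and position must have the same dimension")
  }
  d <- abs(c_coef * leader_pos - m * x)
  leader_pos - a * d
}

# Refresh the four leaders from a candidate pool of (old leaders, population).
# Stable order: fitness first, then pool index, so old leaders win ties and
# the attacker's fitness never worsens.
refresh_leaders <- function(leader_pos, leader_fit, positions, fitness) {
  pool_pos <- rbind(leader_pos, positions)
  pool_fit <- c(leader_fit, fitness)
  ord <- order(pool_fit)  # order() is a stable sort in R
  # a pool smaller than four (tiny populations at init) repeats its worst row
  ord <- ord[pmin(1:4, length(ord))]
  list(positions = pool_pos[ord, , drop = FALSE], fitness = pool_fit[ord])
}

#' Initialize a ChoA population state
#'
#' Draws a uniform-random population inside the bounds, evaluates it, and
#' installs the four best individuals as attacker, barrier, chaser and
#' driver.
#'
#' @param objective Function mapping a position vector to a finite scalar.
#' @param space A [search_space()].
#' @param config A [choa_config()].
#' @param rng Uniform generator: `rng(n)` returns `n` draws in `[0, 1]`.
#'   Defaults to [stats::runif()] so the state of R's RNG governs the run.
#' @return A list of class `chimp_state` with fields `positions`, `fitness`,
#'   `leaders` (positions + fitness of attacker/barrier/chaser/driver),
#'   `iter`, `l`, `map_state`, `n_evals`.
#' @export
choa_init <- function(objective, space, config = choa_config(), rng = stats::runif) {
  P <- config$population
  d <- space$dim
  u <- matrix(rng(P * d), nrow = P, ncol = d, byrow = TRUE)
  positions <- sweep(sweep(u, 2, space$upper - space$lower, "*"),
                     2, space$lower, "+")
  fitness <- apply(positions, 1, function(p) eval_objective(objective, p))
  ld <- refresh_leaders(positions[integer(0), , drop = FALSE], numeric(0),
                        positions, fitness)
  structure(list(positions = positions, fitness = fitness, leaders = ld,
                 iter = 0L, l = config$l0, map_state = config$map_init,
                 n_evals = P),
            class = "chimp_state")
}

eval_objective <- function(objective, pos) {
  val <- objective(pos)
  if (!is.finite(val)) {
    stop(sprintf("objective returned a non-finite value at position (%s)",
                 paste(signif(pos, 6), collapse = ", ")))
  }
  val
}

#' One ChoA iteration
#'
#' For each chimp a uniform `phi` is drawn.  If `phi < prey_prob` the chimp
#' moves to the mean of four leader-directed candidates, each leader using
#' its own `(r1, r2, m)` draws; otherwise the chimp relocates chaotically
#' around the attacker, the move scaled by a fresh chaotic value.  New
#' positions are clamped to the bounds, re-evaluated, and the leaders are
#' refreshed from the pool of old leaders plus the new population.
#'
#' Draw order per chimp (fixed so scripted-generator tests reproduce the
#' update exactly): `phi`; then, on the prey branch, `(r1, r2)` for the
#' attacker, barrier, chaser and driver in that order; on the chaotic
#' branch a single `(r1, r2)` pair.  The chaotic map advances once per
#' `(r1, r2)` pair, immediately after `r2`.
#'
#' @inheritParams choa_init
#' @param state A `chimp_state` from [choa_init()] or a previous step.
#' @return The updated `chimp_state`.
#' @export
choa_step <- function(state, objective, space, config = choa_config(),
                      rng = stats::runif) {
  P <- nrow(state$positions)
  d <- space$dim
  l <- state$l
  map <- config$chaotic_map
  new_pos <- state$positions
  leaders <- state$leaders

  for (j in seq_len(P)) {
    xj <- state$positions[j, ]
    phi <- rng(1)
    if (phi < config$prey_prob) {
      cand_k <- matrix(0, nrow = 4, ncol = d)
      for (k in 1:4) {
        r1 <- rng(1); r2 <- rng(1)
        state$map_state <- chaotic_next(state$map_state, map)
        co <- choa_coefficients(l, r1, r2, state$map_state, config$a_formula)
        cand_k[k, ] <- choa_candidate(leaders$positions[k, ], xj,
                                      co$a, co$c_coef, co$m)
      }
      # fixed double-precision summation order (attacker..driver) so a
      # scripted-generator oracle reproduces the step bitwise
      cand <- (((cand_k[1, ] + cand_k[2, ]) + cand_k[3, ]) + cand_k[4, ]) / 4
    } else {
      r1 <- rng(1); r2 <- rng(1)
      state$map_state <- chaotic_next(state$map_state, map)
      co <- choa_coefficients(l, r1, r2, state$map_state, config$a_formula)
      attacker <- leaders$positions[1, ]
      dist <- abs(co$c_coef * attacker - co$m * xj)
      cand <- attacker - co$a * co$m * dist
    }
    new_pos[j, ] <- clamp_to_bounds(cand, space)
  }

  new_fit <- apply(new_pos, 1, function(p) eval_objective(objective, p))
  state$positions <- new_pos
  state$fitness <- new_fit
  state$leaders <- refresh_leaders(leaders$positions, leaders$fitness,
                                   new_pos, new_fit)
  state$n_evals <- state$n_evals + P
  state$iter <- state$iter + 1L
  state$l <- coeff_schedule(min(state$iter, config$max_iter),
                            config$max_iter, config$l0)
  state
}
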