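#' Default settings for each optimizer
#'
#' Returns the standard parameterization used throughout the package:
#' ChoA with population 10, PSO with 30 particles and cognitive/social
#' factors 0.75, GWO with population 10, WOA with 50 whales; all with 200
#' iterations, 20 runs and move probability 0.5.
#'
#' @param method One of `"choa"`, `"pso"`, `"gwo"`, `"woa"`.
#' @return For `"choa"` a [choa_config()]; otherwise a plain list with
#'   fields `population`, `max_iter`, `runs` and method-specific constants
#'   (`c1`, `c2`, `w_max`, `w_min` for PSO; `spiral_b` for WOA).
#' @export
optimizer_defaults <- function(method = c("choa", "pso", "gwo", "woa")) {
  method <- match.arg(method)
  switch(method,
    choa = choa_config(population = 10L, max_iter = 200L, runs = 20L,
                       prey_prob = 0.5, l0 = 2.5),
    pso  = list(population = 30L, max_iter = 200L, runs = 20L,
                c1 = 0.75, c2 = 0.75, w_max = 0.9, w_min = 0.4),
    gwo  = list(population = 10L, max_iter = 200L, runs = 20L),
    woa  = list(population = 50L, max_iter = 200L, runs = 20L,
                spiral_b = 1))
}

init_population <- function(space, P) {
  u <- matrix(stats::runif(P * space$dim), nrow = P)
  sweep(sweep(u, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
}

make_result <- function(best_position, best_fitness, trace, n_evals, seed) {
  structure(list(best_position = best_position, best_fitness = best_fitness,
                 trace = trace, n_evals = n_evals, seed = seed),
            class = "optimization_result")
}

#' Run a metaheuristic optimizer
#'
#' Minimizes `objective` over a box-constrained space with one of four
#' population metaheuristics: the Chimp Optimization Algorithm (`"choa"`),
#' particle swarm optimization (`"pso"`), the grey wolf optimizer
#' (`"gwo"`) or the whale optimization algorithm (`"woa"`).  All methods
#' start from a uniform-random population, clamp positions to the bounds,
#' and track the best solution ever evaluated, so the returned trace is
#' non-increasing.  Runs are deterministic given `(method, config, seed)`.
#'
#' @param objective Function mapping a position vector to a finite scalar.
#' @param space A [search_space()].
#' @param method One of `"choa"`, `"pso"`, `"gwo"`, `"woa"`.
#' @param config Optimizer settings; defaults to
#'   [optimizer_defaults()] for the chosen method.
#' @param seed Integer seed for the run.
#' @return An `optimization_result`: `best_position`, `best_fitness`,
#'   per-iteration best-so-far `trace` (length `max_iter`), `n_evals`,
#'   `seed`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' sp <- search_space(rep(-10, 5), rep(10, 5))
#' res <- run_optimizer(sphere, sp, "choa",
#'                      choa_config(max_iter = 20L), seed = 1)
#' res$best_fitness <= res$trace[1]
#' @export
run_optimizer <- function(objective, space,
                          method = c("choa", "pso", "gwo", "woa"),
                          config = NULL, seed = 1L) {
  method <- match.arg(method)
  if (is.null(config)) config <- optimizer_defaults(method)
  set.seed(seed)
  switch(method,
         choa = run_choa(objective, space, config, seed),
         pso  = run_pso(objective, space, config, seed),
         gwo  = run_gwo(objective, space, config, seed),
         woa  = run_woa(objective, space, config, seed))
}

run_choa <- function(objective, space, config, seed) {
  state <- choa_init(objective, space, config)
  N <- config$max_iter
  trace <- numeric(N)
  for (n in seq_len(N)) {
    state <- choa_step(state, objective, space, config)
    trace[n] <- state$leaders$fitness[1]
  }
  make_result(state$leaders$positions[1, ], state$leaders$fitness[1],
              trace, state$n_evals, seed)
}

run_pso <- function(objective, space, config, seed) {
  P <- config$population; N <- config$max_iter; d <- space$dim
  X <- init_population(space, P)
  V <- matrix(0, nrow = P, ncol = d)
  fit <- apply(X, 1, function(p) eval_objective(objective, p))
  pbest <- X; pbest_fit <- fit
  g <- which.min(fit); gbest <- X[g, ]; gbest_fit <- fit[g]
  n_evals <- P
  trace <- numeric(N)
  for (n in seq_len(N)) {
    w <- config$w_max - (config$w_max - config$w_min) * (n - 1) / max(N - 1, 1)
    r1 <- matrix(stats::runif(P * d), nrow = P)
    r2 <- matrix(stats::runif(P * d), nrow = P)
    V <- w * V + config$c1 * r1 * (pbest - X) +
      config$c2 * r2 * sweep(-X, 2, gbest, "+")
    X <- X + V
    X <- t(apply(X, 1, clamp_to_bounds, space = space))
    fit <- apply(X, 1, function(p) eval_objective(objective, p))
    n_evals <- n_evals + P
    improved <- fit < pbest_fit
    pbest[improved, ] <- X[improved, , drop = FALSE]
    pbest_fit[improved] <- fit[improved]
    g <- which.min(pbest_fit)
    if (pbest_fit[g] < gbest_fit) { gbest <- pbest[g, ]; gbest_fit <- pbest_fit[g] }
    trace[n] <- gbest_fit
  }
  make_result(gbest, gbest_fit, trace, n_evals, seed)
}

run_gwo <- function(objective, space, config, seed) {
  P <- config$population; N <- config$max_iter; d <- space$dim
  X <- init_population(space, P)
  fit <- apply(X, 1, function(p) eval_objective(objective, p))
  # alpha/beta/delta kept as the three best solutions ever seen; a pool
  # smaller than three repeats its worst member
  ord <- order(fit)[pmin(1:3, P)]
  L <- X[ord, , drop = FALSE]; Lfit <- fit[ord]
  n_evals <- P
  trace <- numeric(N)
  for (n in seq_len(N)) {
    a <- 2 - 2 * (n - 1) / max(N - 1, 1)
    for (j in seq_len(P)) {
      cand <- numeric(d)
      for (k in 1:3) {
        r1 <- stats::runif(d); r2 <- stats::runif(d)
        A <- 2 * a * r1 - a
        C <- 2 * r2
        D <- abs(C * L[k, ] - X[j, ])
        cand <- cand + (L[k, ] - A * D)
      }
      X[j, ] <- clamp_to_bounds(cand / 3, space)
    }
    fit <- apply(X, 1, function(p) eval_objective(objective, p))
    n_evals <- n_evals + P
    pool <- rbind(L, X); pool_fit <- c(Lfit, fit)
    ord <- order(pool_fit)[pmin(1:3, length(pool_fit))]
    L <- pool[ord, , drop = FALSE]; Lfit <- pool_fit[ord]
    trace[n] <- Lfit[1]
  }
  make_result(L[1, ], Lfit[1], trace, n_evals, seed)
}

run_woa <- function(objective, space, config, seed) {
  P <- config$population; N <- config$max_iter; d <- space$dim
  b <- config$spiral_b
  X <- init_population(space, P)
  fit <- apply(X, 1, function(p) eval_objective(objective, p))
  g <- which.min(fit); best <- X[g, ]; best_fit <- fit[g]
  n_evals <- P
  trace <- numeric(N)
  for (n in seq_len(N)) {
    a <- 2 - 2 * (n - 1) / max(N - 1, 1)
    for (j in seq_len(P)) {
      p <- stats::runif(1)
      if (p < 0.5) {
        r1 <- stats::runif(d); r2 <- stats::runif(d)
        A <- 2 * a * r1 - a
        C <- 2 * r2
        if (max(abs(A)) < 1) {
          D <- abs(C * best - X[j, ])
          cand <- best - A * D
        } else {
          rj <- sample.int(P, 1L)
          D <- abs(C * X[rj, ] - X[j, ])
          cand <- X[rj, ] - A * D
        }
      } else {
        lsp <- stats::runif(1, -1, 1)
        D <- abs(best - X[j, ])
        cand <- D * exp(b * lsp) * cos(2 * pi * lsp) + best
      }
      X[j, ] <- clamp_to_bounds(cand, space)
    }
    fit <- apply(X, 1, function(p) eval_objective(objective, p))
    n_evals <- n_evals + P
    g <- which.min(fit)
    if (fit[g] < best_fit) { best <- X[g, ]; best_fit <- fit[g] }
    trace[n] <- best_fit
  }
  make_result(best, best_fit, trace, n_evals, seed)
}
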