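sphere <- function(x) sum(x^2)

test_that("coefficient schedule is the stated line from l0 to 0", {
  expect_equal(coeff_schedule(0, 200, 2.5), 2.5)
  expect_equal(coeff_schedule(200, 200, 2.5), 0)
  expect_equal(coeff_schedule(100, 200, 2.5), 1.25)
  iters <- 0:50
  ls <- vapply(iters, coeff_schedule, 1, max_iter = 50, l0 = 2.5)
  expect_true(all(diff(ls) < 0))
  expect_error(coeff_schedule(-1, 10, 2.5), "iter")
  expect_error(coeff_schedule(11, 10, 2.5), "iter")
})

test_that("chaotic maps stay in the unit interval", {
  expect_equal(chaotic_next(0.7, "logistic"), 0.84)
  expect_equal(chaotic_next(0, "logistic"), 0)
  expect_equal(chaotic_next(0.25, "tent"), 0.5)
  expect_error(chaotic_next(1.2, "logistic"), "map_state")
  for (map in c("logistic", "tent")) {
    x <- 0.137
    for (i in 1:200) {
      x <- chaotic_next(x, map)
      expect_true(x >= 0 && x <= 1)
    }
  }
})

test_that("update coefficients follow both attack-coefficient formulas", {
  co <- choa_coefficients(2.5, 1, 0.5, 0.3, "paper")
  expect_equal(co$a, 4)
  expect_equal(co$c_coef, 1)
  expect_equal(co$m, 0.3)
  expect_equal(choa_coefficients(2.5, 1, 0.5, 0.3, "original")$a, 2.5)
  co0 <- choa_coefficients(0, 0.5, 0, 1, "paper")
  expect_equal(co0$a, -1)
  expect_equal(co0$c_coef, 0)
  set.seed(3)
  for (i in 1:50) {
    co <- choa_coefficients(runif(1, 0, 2.5), runif(1), runif(1), runif(1))
    expect_true(co$c_coef >= 0 && co$c_coef <= 2)
  }
})

test_that("leader-directed candidates follow the distance rule", {
  expect_equal(choa_candidate(c(2), c(1), a = 0.5, c_coef = 1, m = 1), 1.5)
  leader <- c(0.3, -0.2)
  expect_equal(choa_candidate(leader, leader, a = 7, c_coef = 1, m = 1),
               leader)
  # d = |2 * leader - 0.5 * 0| = (2, 2); candidate = leader - 1 * d
  expect_equal(choa_candidate(c(1, -1), c(0, 0), a = 1, c_coef = 2, m = 0.5),
               c(-1, -3))
  expect_error(choa_candidate(c(1, 2), c(1), 1, 1, 1), "dimension")
})

test_that("bound clamping is correct and idempotent", {
  sp <- search_space(c(-10, -10), c(10, 10))
  expect_equal(clamp_to_bounds(c(11, -11), sp), c(10, -10))
  expect_equal(clamp_to_bounds(c(3, -4), sp), c(3, -4))
  x <- c(25, -0.3)
  expect_equal(clamp_to_bounds(clamp_to_bounds(x, sp), sp),
               clamp_to_bounds(x, sp))
})

test_that("a population sitting at the optimum does not move", {
  sp <- search_space(rep(-5, 2), rep(5, 2))
  cfg <- choa_config(population = 4L, max_iter = 10L, map_init = 0)
  # all draws phi = 0 (< prey_prob), then r1/r2 pairs; m stays at the
  # logistic fixed point 0
  rng <- scripted_rng(rep(c(0, rep(0.5, 8)), 4))
  state <- list(positions = matrix(0, 4, 2), fitness = rep(0, 4),
                leaders = list(positions = matrix(0, 4, 2),
                               fitness = rep(0, 4)),
                iter = 0L, l = 2.5, map_state = 0, n_evals = 4L)
  out <- choa_step(state, sphere, sp, cfg, rng)
  expect_equal(out$positions, matrix(0, 4, 2))
})

test_that("one step matches the hand-stepped substitution exactly", {
  set.seed(11)
  P <- 3; d <- 2
  sp <- search_space(rep(-10, d), rep(10, d))
  cfg <- choa_config(population = P, max_iter = 20L, map_init = 0.7)
  positions <- matrix(runif(P * d, -10, 10), P, d)
  fitness <- apply(positions, 1, sphere)
  ord <- order(fitness)[pmin(1:4, P)]
  leaders <- list(positions = positions[ord, , drop = FALSE],
                  fitness = fitness[ord])
  # scripted draws: chimp 1 prey branch (phi=0.2), chimp 2 chaotic
  # (phi=0.9), chimp 3 prey again
  draws <- c(0.2, 0.11, 0.52, 0.93, 0.34, 0.75, 0.16, 0.57, 0.98,
             0.9, 0.41, 0.82,
             0.2, 0.23, 0.64, 0.05, 0.46, 0.87, 0.28, 0.69, 0.10)
  state <- list(positions = positions, fitness = fitness, leaders = leaders,
                iter = 0L, l = 2.5, map_state = 0.7, n_evals = P)
  stepped <- choa_step(state, sphere, sp, cfg, scripted_rng(draws))
  expected <- oracle_choa_step(positions, leaders$positions, draws,
                               l = 2.5, prey_prob = 0.5, map_state = 0.7,
                               lower = sp$lower, upper = sp$upper,
                               a_formula = "paper")
  expect_equal(stepped$positions, expected, tolerance = 0)
})

test_that("the attacker never worsens across steps", {
  sp <- search_space(rep(-10, 3), rep(10, 3))
  cfg <- choa_config(population = 6L, max_iter = 30L)
  set.seed(5)
  state <- choa_init(sphere, sp, cfg)
  prev <- state$leaders$fitness[1]
  for (i in 1:30) {
    state <- choa_step(state, sphere, sp, cfg)
    expect_lte(state$leaders$fitness[1], prev)
    expect_true(all(diff(state$leaders$fitness) >= 0))
    prev <- state$leaders$fitness[1]
  }
})

test_that("every optimizer produces monotone traces within bounds", {
  sp <- search_space(rep(-10, 5), rep(10, 5))
  for (method in c("choa", "pso", "gwo", "woa")) {
    cfg <- optimizer_defaults(method)
    cfg$max_iter <- 30L
    for (seed in 1:5) {
      visited <- new.env(parent = emptyenv()); visited$bad <- FALSE
      obj <- function(x) {
        if (any(x < sp$lower - 1e-12) || any(x > sp$upper + 1e-12)) {
          visited$bad <- TRUE
        }
        sphere(x)
      }
      res <- run_optimizer(obj, sp, method, cfg, seed = seed)
      expect_true(all(diff(res$trace) <= 0))
      expect_equal(res$best_fitness, res$trace[length(res$trace)])
      expect_false(visited$bad)
      expect_true(all(res$best_position >= sp$lower &
                        res$best_position <= sp$upper))
    }
  }
})

test_that("fixed seeds reproduce traces bitwise", {
  sp <- search_space(rep(-10, 4), rep(10, 4))
  for (method in c("choa", "pso", "gwo", "woa")) {
    cfg <- optimizer_defaults(method)
    cfg$max_iter <- 15L
    a <- run_optimizer(sphere, sp, method, cfg, seed = 42)
    b <- run_optimizer(sphere, sp, method, cfg, seed = 42)
    expect_identical(a$trace, b$trace)
    expect_identical(a$best_position, b$best_position)
  }
})

test_that("a degenerate budget returns the single evaluated point", {
  sp <- search_space(rep(-2, 2), rep(2, 2))
  for (method in c("pso", "gwo", "woa")) {
    cfg <- optimizer_defaults(method)
    cfg$population <- 1L; cfg$max_iter <- 1L
    res <- run_optimizer(sphere, sp, method, cfg, seed = 9)
    expect_equal(length(res$trace), 1L)
    expect_equal(res$best_fitness, sphere(res$best_position))
  }
  res <- run_optimizer(sphere, sp, "choa",
                       choa_config(population = 2L, max_iter = 1L), seed = 9)
  expect_equal(length(res$trace), 1L)
  expect_equal(res$best_fitness, sphere(res$best_position))
})

test_that("a non-finite objective names the offending position", {
  sp <- search_space(c(-1, -1), c(1, 1))
  bad <- function(x) if (x[1] > -2) NaN else sum(x^2)
  expect_error(run_optimizer(bad, sp, "choa",
                             choa_config(population = 2L, max_iter = 2L),
                             seed = 1),
               "non-finite")
})
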