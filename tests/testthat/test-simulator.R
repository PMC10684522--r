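test_that("valve profiles have one inhalation-exhalation transition", {
  set.seed(4)
  for (i in 1:20) {
    p <- valve_profile()
    expect_equal(sum(diff(p$u_out) != 0), 1L)
    expect_true(all(p$u_out[1] == 0))
    expect_true(all(p$u_in[p$u_out == 1] == 0))
    expect_true(all(p$u_in >= 0 & p$u_in <= 100))
    expect_equal(p$time_step[1], 0)
    expect_true(all(diff(p$time_step) > 0))
  }
  set.seed(10); a <- valve_profile()
  set.seed(10); b <- valve_profile()
  expect_identical(a, b)
})

test_that("a closed inspiratory valve with open expiratory valve holds PEEP", {
  lung <- lung_config(R = 20, C = 20, peep = 5, noise_sd = 0)
  n <- 80
  prof <- list(time_step = seq(0, 3, length.out = n),
               u_in = rep(0, n), u_out = rep(1L, n))
  b <- simulate_breath(lung, prof)
  expect_equal(b$pressure, rep(5, n))
})

test_that("constant inflow with closed expiratory valve raises pressure", {
  lung <- lung_config(R = 20, C = 20, peep = 5, noise_sd = 0)
  n <- 80
  prof <- list(time_step = seq(0, 3, length.out = n),
               u_in = rep(50, n), u_out = rep(0L, n))
  b <- simulate_breath(lung, prof)
  expect_true(all(diff(b$pressure) > 0))
})

test_that("volume equals the discrete integral of net flow", {
  # with zero noise the net flow can be recovered from the recorded
  # pressure: dV/dt = (P - PEEP - 1000 V / C) / R
  set.seed(8)
  for (i in 1:5) {
    lung <- lung_config(R = sample(c(5, 20, 50), 1),
                        C = sample(c(10, 20, 50), 1), noise_sd = 0)
    prof <- valve_profile()
    b <- simulate_breath(lung, prof)
    V <- attr(b, "volume")
    dt <- diff(prof$time_step); dt <- c(dt[1], dt)
    dvdt <- (b$pressure - lung$peep - 1000 * V / lung$C) / lung$R
    expect_lt(max(abs(V - cumsum(dvdt * dt))), 1e-9)
    expect_true(all(V >= 0))
  }
})

test_that("doubling compliance halves the elastic pressure term", {
  # input-driven flow only (expiratory valve closed throughout): the
  # volume path is then independent of C and the elastic term scales as 1/C
  set.seed(12)
  n <- 80
  prof <- list(time_step = seq(0, 3, length.out = n),
               u_in = pmin(100, pmax(0, cumsum(rnorm(n, 1, 5)))),
               u_out = rep(0L, n))
  l1 <- lung_config(R = 20, C = 20, noise_sd = 0)
  l2 <- lung_config(R = 20, C = 40, noise_sd = 0)
  b1 <- simulate_breath(l1, prof)
  b2 <- simulate_breath(l2, prof)
  V1 <- attr(b1, "volume"); V2 <- attr(b2, "volume")
  expect_equal(V1, V2, tolerance = 1e-12)  # same inputs, same flows
  elastic1 <- 1000 * V1 / l1$C
  elastic2 <- 1000 * V2 / l2$C
  expect_equal(elastic1, 2 * elastic2, tolerance = 1e-12)
})

test_that("explicit Euler agrees with a 10x finer integration", {
  lung <- lung_config(R = 20, C = 20, peep = 5, noise_sd = 0)
  n <- 80
  prof <- list(time_step = seq(0, 3, length.out = n),
               u_in = rep(50, n), u_out = rep(0L, n))
  coarse <- simulate_breath(lung, prof)
  nf <- 10 * n
  prof_f <- list(time_step = seq(0, 3, length.out = nf),
                 u_in = rep(50, nf), u_out = rep(0L, nf))
  fine <- simulate_breath(lung, prof_f)
  pick <- seq(10, nf, by = 10)
  rel <- abs(fine$pressure[pick] - coarse$pressure) / fine$pressure[pick]
  expect_lt(max(rel), 0.01)
})

test_that("generated datasets are stratified, reproducible and schema-valid", {
  d <- generate_dataset(9, seed = 1)
  expect_equal(names(d), c("id", "breath_id", "R", "C", "time_step",
                           "u_in", "u_out", "pressure"))
  expect_equal(nrow(d), 9 * 80)
  pairs <- unique(d[c("breath_id", "R", "C")])
  expect_equal(nrow(unique(pairs[c("R", "C")])), 9L)

  d2 <- generate_dataset(9, seed = 1)
  expect_identical(d, d2)

  expect_equal(d$id, seq_len(nrow(d)))
  for (bid in unique(d$breath_id)) {
    rows <- d[d$breath_id == bid, ]
    expect_true(all(diff(rows$time_step) > 0))
    expect_true(all(rows$u_in >= 0 & rows$u_in <= 100))
    expect_true(all(rows$u_out %in% c(0, 1)))
    expect_true(all(is.finite(rows$pressure)))
  }
  expect_error(generate_dataset(0), "n_breaths")
})

test_that("open-valve pressures sit below closed-valve pressures", {
  d <- generate_dataset(60, seed = 5)
  expect_lt(median(d$pressure[d$u_out == 1]),
            median(d$pressure[d$u_out == 0]))
})

test_that("distinct lung settings shape distinct pressure distributions", {
  d <- generate_dataset(90, seed = 6)
  groups <- split(d$pressure, paste(d$R, d$C))
  expect_equal(length(groups), 9L)
  ks <- outer(seq_along(groups), seq_along(groups),
              Vectorize(function(i, j) {
                if (i >= j) return(NA_real_)
                suppressWarnings(
                  stats::ks.test(groups[[i]], groups[[j]])$statistic)
              }))
  expect_true(all(ks[upper.tri(ks)] > 0))
})
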