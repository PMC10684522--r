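test_that("zero-weight cell reduces to the closed-form gate values", {
  H <- 2L; I <- 3L
  layer <- list(W = matrix(0, 4 * H, H + I), B = numeric(4 * H))
  out <- lstm_cell(rnorm(I), numeric(H), numeric(H), layer)
  # sigma(0) = 0.5 and tanh(0) = 0, so the candidate is 0 and h stays 0
  expect_equal(out$c, c(0, 0))
  expect_equal(out$h, c(0, 0))
  out2 <- lstm_cell(rnorm(I), numeric(H), c(1, 1), layer)
  expect_equal(out2$c, c(0.5, 0.5))
  expect_equal(out2$h, rep(0.5 * tanh(0.5), 2))
})

test_that("cell and forward match the scalar-loop oracle", {
  set.seed(101)
  for (rep in 1:25) {
    H <- sample(1:4, 1); I <- sample(1:3, 1)
    params <- lstm_init_params(I, H, 1)
    g <- split_layer(params$layers[[1]])
    x <- rnorm(I); h0 <- rnorm(H, sd = 0.5); c0 <- rnorm(H, sd = 0.5)
    mine <- lstm_cell(x, h0, c0, params$layers[[1]])
    ref <- oracle_lstm_cell(x, h0, c0, g$W_f, g$W_i, g$W_c, g$W_o,
                            g$B_f, g$B_i, g$B_c, g$B_o)
    expect_equal(mine$h, ref$h, tolerance = 1e-12)
    expect_equal(mine$c, ref$c, tolerance = 1e-12)

    T_len <- sample(2:6, 1)
    L <- sample(1:2, 1)
    params <- lstm_init_params(I, H, L)
    xs <- matrix(rnorm(I * T_len), I, T_len)
    mine <- lstm_forward(params, xs)
    ref <- oracle_lstm_forward(xs, lapply(params$layers, split_layer),
                               params$w_y, params$b_y)
    expect_lt(max(abs(mine - ref)), 1e-12)
  }
})

test_that("forward pass is causal and unrolls correctly", {
  set.seed(7)
  params <- lstm_init_params(2, 3, 1)
  x1 <- matrix(rnorm(2), 2, 1)
  single <- lstm_forward(params, x1)
  cell <- lstm_cell(x1[, 1], numeric(3), numeric(3), params$layers[[1]])
  expect_equal(single, sum(params$w_y * cell$h) + params$b_y)

  xs <- matrix(rnorm(2 * 10), 2, 10)
  full <- lstm_forward(params, xs)
  expect_equal(lstm_forward(params, xs[, 1:6, drop = FALSE]), full[1:6])

  # two stacked layers equal the manual composition of two one-layer passes
  params2 <- lstm_init_params(2, 3, 2)
  inner <- structure(list(layers = params2$layers[1],
                          w_y = numeric(3), b_y = 0,
                          n_input = 2L, n_hidden = 3L, n_layers = 1L),
                     class = "lstm_params")
  # run layer 1 alone by reading hidden states through the oracle
  g1 <- split_layer(params2$layers[[1]])
  h <- numeric(3); cc <- numeric(3)
  h_seq <- matrix(0, 3, 10)
  for (t in 1:10) {
    st <- oracle_lstm_cell(xs[, t], h, cc, g1$W_f, g1$W_i, g1$W_c, g1$W_o,
                           g1$B_f, g1$B_i, g1$B_c, g1$B_o)
    h <- st$h; cc <- st$c
    h_seq[, t] <- h
  }
  outer <- structure(list(layers = params2$layers[2],
                          w_y = params2$w_y, b_y = params2$b_y,
                          n_input = 3L, n_hidden = 3L, n_layers = 1L),
                     class = "lstm_params")
  expect_equal(lstm_forward(params2, xs), lstm_forward(outer, h_seq),
               tolerance = 1e-12)
})

test_that("gate activations respect their ranges", {
  set.seed(21)
  params <- lstm_init_params(3, 4, 1)
  h <- numeric(4); cc <- numeric(4)
  for (t in 1:50) {
    st <- lstm_cell(rnorm(3, sd = 3), h, cc, params$layers[[1]])
    h <- st$h; cc <- st$c
    expect_true(all(abs(h) < 1))  # |h| = |o| * |tanh(c)| < 1
  }
})

test_that("mse matches its definition", {
  expect_equal(mse(c(1, 2), c(1, 2)), 0)
  expect_equal(mse(c(0, 0), c(1, 1)), 1)
  expect_equal(mse(c(0, 0, 0), c(1, 2, 3)), 14 / 3)
  expect_error(mse(1:3, 1:2), "length")
})

test_that("gradients match central finite differences", {
  set.seed(33)
  params <- lstm_init_params(3, 2, 2)
  x <- matrix(rnorm(3 * 3), 3, 3)  # 3 inputs, 3 time steps
  y <- rnorm(3)
  an <- lstm_loss(params, x, y, grad = TRUE)
  eps <- 1e-5
  check_entry <- function(getter, setter, analytic) {
    p_plus <- setter(params, getter(params) + eps)
    p_minus <- setter(params, getter(params) - eps)
    fd <- (lstm_loss(p_plus, x, y)$loss - lstm_loss(p_minus, x, y)$loss) /
      (2 * eps)
    expect_lt(abs(fd - analytic) / max(abs(fd), abs(analytic), 1e-8), 1e-4)
  }
  for (l in 1:2) {
    Wd <- dim(params$layers[[l]]$W)
    set.seed(100 + l)
    for (pick in 1:8) {
      i <- sample(Wd[1], 1); j <- sample(Wd[2], 1)
      check_entry(function(p) p$layers[[l]]$W[i, j],
                  function(p, v) { p$layers[[l]]$W[i, j] <- v; p },
                  an$dW[[l]][i, j])
      k <- sample(length(params$layers[[l]]$B), 1)
      check_entry(function(p) p$layers[[l]]$B[k],
                  function(p, v) { p$layers[[l]]$B[k] <- v; p },
                  an$dB[[l]][k])
    }
  }
  for (k in seq_along(params$w_y)) {
    check_entry(function(p) p$w_y[k],
                function(p, v) { p$w_y[k] <- v; p },
                an$dwy[k])
  }
  check_entry(function(p) p$b_y, function(p, v) { p$b_y <- v; p }, an$dby)
})

test_that("training learns a linear toy task and is reproducible", {
  d <- toy_linear_breaths(50, seed = 42)
  cfg <- train_config(epochs = 30, learning_rate = 5e-3, hidden_units = 8,
                      layers = 1, batch_size = 16, seed = 3)
  m1 <- vent_lstm(d, cfg)
  expect_lt(m1$loss_trace[30], m1$loss_trace[1])
  m2 <- vent_lstm(d, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params, m2$params)
  # and the fit is actually decent on this noiseless linear target
  expect_lt(mse(d$pressure, predict(m1, d)), stats::var(d$pressure))
})

test_that("a zero learning rate freezes the loss", {
  d <- toy_linear_breaths(10, seed = 9)
  cfg <- train_config(epochs = 5, learning_rate = 0, hidden_units = 4,
                      layers = 1, batch_size = 4, seed = 1)
  m <- vent_lstm(d, cfg)
  expect_equal(max(m$loss_trace) - min(m$loss_trace), 0)
})

test_that("empty or mismatched inputs error cleanly", {
  params <- lstm_init_params(2, 2, 1)
  expect_error(lstm_forward(params, matrix(0, 3, 4)), "n_input")
  expect_error(lstm_train(list(), list(), train_config()), "non-empty")
})
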