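# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: scalar loops, literal formulas.

# Scripted uniform generator: returns queued values in order.
scripted_rng <- function(values) {
  queue <- as.numeric(values)
  function(n) {
    if (n > length(queue)) stop("scripted rng exhausted")
    out <- queue[seq_len(n)]
    queue <<- queue[-seq_len(n)]
    out
  }
}

# Per-equation scalar-loop LSTM cell: gates computed element by element
# from per-gate weight matrices.
oracle_lstm_cell <- function(x, h_prev, c_prev,
                             W_f, W_i, W_c, W_o, B_f, B_i, B_c, B_o) {
  H <- length(h_prev)
  a <- c(h_prev, x)
  sig <- function(v) 1 / (1 + exp(-v))
  h_t <- numeric(H); c_t <- numeric(H)
  for (u in seq_len(H)) {
    zf <- sum(W_f[u, ] * a) + B_f[u]
    zi <- sum(W_i[u, ] * a) + B_i[u]
    zc <- sum(W_c[u, ] * a) + B_c[u]
    zo <- sum(W_o[u, ] * a) + B_o[u]
    f <- sig(zf); i <- sig(zi); g <- tanh(zc); o <- sig(zo)
    c_t[u] <- f * c_prev[u] + i * g
    h_t[u] <- o * tanh(c_t[u])
  }
  list(h = h_t, c = c_t)
}

# Full forward pass through stacked layers plus linear readout, all in
# scalar loops.  `gates` is a list per layer of per-gate matrices.
oracle_lstm_forward <- function(x_seq, gates, w_y, b_y) {
  H <- length(w_y)
  L <- length(gates)
  T_len <- ncol(x_seq)
  h <- replicate(L, numeric(H), simplify = FALSE)
  cc <- replicate(L, numeric(H), simplify = FALSE)
  preds <- numeric(T_len)
  for (t in seq_len(T_len)) {
    inp <- x_seq[, t]
    for (l in seq_len(L)) {
      g <- gates[[l]]
      st <- oracle_lstm_cell(inp, h[[l]], cc[[l]],
                             g$W_f, g$W_i, g$W_c, g$W_o,
                             g$B_f, g$B_i, g$B_c, g$B_o)
      h[[l]] <- st$h; cc[[l]] <- st$c
      inp <- st$h
    }
    preds[t] <- sum(w_y * h[[L]]) + b_y
  }
  preds
}

# Split a fused ventlstm layer into per-gate matrices for the oracle.
split_layer <- function(layer) {
  H <- length(layer$B) / 4L
  idx <- function(k) ((k - 1L) * H + 1L):(k * H)
  list(W_f = layer$W[idx(1), , drop = FALSE], B_f = layer$B[idx(1)],
       W_i = layer$W[idx(2), , drop = FALSE], B_i = layer$B[idx(2)],
       W_c = layer$W[idx(3), , drop = FALSE], B_c = layer$B[idx(3)],
       W_o = layer$W[idx(4), , drop = FALSE], B_o = layer$B[idx(4)])
}

# Hand-stepped ChoA iteration: literal substitution into the distance /
# candidate / mean-update formulas with an explicitly tracked logistic
# map and the documented draw order (phi; then per leader r1, r2, map).
# Returns the new positions only; no package functions are used.
oracle_choa_step <- function(positions, leaders, draws, l, prey_prob,
                             map_state, lower, upper,
                             a_formula = c("paper", "original")) {
  a_formula <- match.arg(a_formula)
  P <- nrow(positions); d <- ncol(positions)
  take <- local({
    i <- 0L
    function() { i <<- i + 1L; draws[i] }
  })
  new_pos <- positions
  for (j in seq_len(P)) {
    phi <- take()
    xj <- positions[j, ]
    if (phi < prey_prob) {
      acc <- numeric(d)
      for (k in 1:4) {
        r1 <- take(); r2 <- take()
        map_state <- 4 * map_state * (1 - map_state)
        a <- if (a_formula == "paper") 2 * l * r1 - 1 else 2 * l * r1 - l
        cc <- 2 * r2
        m <- map_state
        dist <- abs(cc * leaders[k, ] - m * xj)
        acc <- acc + (leaders[k, ] - a * dist)
      }
      cand <- acc / 4
    } else {
      r1 <- take(); r2 <- take()
      map_state <- 4 * map_state * (1 - map_state)
      a <- if (a_formula == "paper") 2 * l * r1 - 1 else 2 * l * r1 - l
      cc <- 2 * r2
      m <- map_state
      dist <- abs(cc * leaders[1, ] - m * xj)
      cand <- leaders[1, ] - a * m * dist
    }
    new_pos[j, ] <- pmin(pmax(cand, lower), upper)
  }
  new_pos
}

# Small learnable dataset: pressure is a scaled copy of u_in, so a short
# training run must reduce the loss.
toy_linear_breaths <- function(n_breaths = 50, seed = 42) {
  d <- generate_dataset(n_breaths, seed = seed, noise_sd = 0)
  d$pressure <- 0.5 * d$u_in
  d
}
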