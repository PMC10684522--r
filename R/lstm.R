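#' Assemble one LSTM layer from per-gate matrices
#'
#' Fuses the forget, input, candidate and output gate weights into the
#' single matrix representation used internally (row blocks in that
#' order).  Every gate acts on the concatenation `[h_prev, x_t]`, hidden
#' part first.
#'
#' @param W_f,W_i,W_c,W_o Gate weight matrices, each `H x (H + I)`.
#' @param B_f,B_i,B_c,B_o Gate bias vectors, each length `H`.
#' @return A list with fused fields `W` (`4H x (H + I)`) and `B` (`4H`).
#' @export
lstm_layer <- function(W_f, W_i, W_c, W_o, B_f, B_i, B_c, B_o) {
  dims <- vapply(list(W_f, W_i, W_c, W_o), function(m) dim(m), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all gate weight matrices must share the same shape")
  }
  H <- dims[1, 1]
  if (any(vapply(list(B_f, B_i, B_c, B_o), length, 1L) != H)) {
    stop("gate bias vectors must have length equal to the hidden size")
  }
  list(W = rbind(W_f, W_i, W_c, W_o), B = c(B_f, B_i, B_c, B_o))
}

# Split a fused layer back into its per-gate pieces.
layer_gates <- function(layer) {
  H <- length(layer$B) / 4L
  idx <- function(k) ((k - 1L) * H + 1L):(k * H)
  list(W_f = layer$W[idx(1), , drop = FALSE], B_f = layer$B[idx(1)],
       W_i = layer$W[idx(2), , drop = FALSE], B_i = layer$B[idx(2)],
       W_c = layer$W[idx(3), , drop = FALSE], B_c = layer$B[idx(3)],
       W_o = layer$W[idx(4), , drop = FALSE], B_o = layer$B[idx(4)])
}

#' Initialize LSTM parameters
#'
#' Weights are drawn uniformly in `+/- 1/sqrt(fan_in)` from R's current
#' random stream; biases start at zero.  A linear readout (`w_y`, `b_y`)
#' maps the top layer's hidden state to one pressure value per time step.
#'
#' @param n_input Number of input features per time step.
#' @param n_hidden Hidden units per layer (N_HU).
#' @param n_layers Number of stacked layers (N_L).
#' @return A list of class `lstm_params` with `layers` (each a fused
#'   layer, see [lstm_layer()]), `w_y`, `b_y`, and the three sizes.
#' @export
lstm_init_params <- function(n_input, n_hidden, n_layers = 1L) {
  stopifnot(n_input >= 1, n_hidden >= 1, n_layers >= 1)
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    I <- if (l == 1L) n_input else n_hidden
    fan_in <- n_hidden + I
    r <- 1 / sqrt(fan_in)
    layers[[l]] <- list(
      W = matrix(stats::runif(4 * n_hidden * fan_in, -r, r),
                 nrow = 4 * n_hidden),
      B = numeric(4 * n_hidden))
  }
  r <- 1 / sqrt(n_hidden)
  structure(list(layers = layers,
                 w_y = stats::runif(n_hidden, -r, r), b_y = 0,
                 n_input = as.integer(n_input),
                 n_hidden = as.integer(n_hidden),
                 n_layers = as.integer(n_layers)),
            class = "lstm_params")
}

#' One LSTM cell update
#'
#' Pure-R single-step evaluation of the gate equations: forget gate
#' `f = sigmoid(W_f [h, x] + B_f)`, input gate `i = sigmoid(W_i [h, x] + B_i)`,
#' candidate `g = tanh(W_c [h, x] + B_c)`, output gate
#' `o = sigmoid(W_o [h, x] + B_o)`, then `c_t = f * c_prev + i * g` and
#' `h_t = o * tanh(c_t)`.
#'
#' @param x_t Input vector at the current time step.
#' @param h_prev,c_prev Previous hidden and cell state vectors (length `H`).
#' @param layer A fused layer (`W`, `B`; see [lstm_layer()]).
#' @return A list with the new `h` and `c` vectors.
#' @examples
#' H <- 2; I <- 3
#' layer <- list(W = matrix(0, 4 * H, H + I), B = numeric(4 * H))
#' lstm_cell(rnorm(I), numeric(H), numeric(H), layer)$h  # all zero
#' @export
lstm_cell <- function(x_t, h_prev, c_prev, layer) {
  H <- length(layer$B) / 4L
  if (length(h_prev) != H || length(c_prev) != H) {
    stop("h_prev and c_prev must have length equal to the hidden size")
  }
  if (ncol(layer$W) != H + length(x_t)) {
    stop("input size does not match the layer's weight matrix")
  }
  z <- drop(layer$W %*% c(h_prev, x_t)) + layer$B
  idx <- function(k) ((k - 1L) * H + 1L):(k * H)
  sig <- function(v) 1 / (1 + exp(-v))
  f <- sig(z[idx(1)])
  i <- sig(z[idx(2)])
  g <- tanh(z[idx(3)])
  o <- sig(z[idx(4)])
  c_t <- f * c_prev + i * g
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t)
}

# Coerce x to a cube (I x B x T).  Accepts a single I x T matrix or a
# 3-d array already in cube layout.
as_input_cube <- function(x, n_input) {
  if (is.matrix(x)) {
    if (nrow(x) != n_input) stop("input matrix must have n_input rows")
    array(x, dim = c(nrow(x), 1L, ncol(x)))
  } else if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[1] != n_input) stop("input array must have n_input rows")
    x
  } else {
    stop("x must be an n_input x T matrix or an n_input x B x T array")
  }
}

#' LSTM forward pass
#'
#' Runs the stacked LSTM over a sequence (or a batch of equal-length
#' sequences) and applies the linear readout at every time step.  The pass
#' is causal: the prediction at step `t` depends only on inputs up to `t`.
#'
#' @param params An `lstm_params` object.
#' @param x Either an `n_input x T` matrix (one sequence) or an
#'   `n_input x B x T` array (a batch).
#' @return A numeric vector of length `T` for a single sequence, or a
#'   `T x B` matrix for a batch.
#' @export
lstm_forward <- function(params, x) {
  single <- is.matrix(x)
  cube <- as_input_cube(x, params$n_input)
  if (dim(cube)[3] < 1L) stop("sequence must be non-empty")
  out <- lstm_pass_cpp(lapply(params$layers, `[[`, "W"),
                       lapply(params$layers, `[[`, "B"),
                       params$w_y, params$b_y, cube,
                       matrix(0, nrow = dim(cube)[3], ncol = dim(cube)[2]),
                       FALSE)
  if (single) drop(out$preds) else out$preds
}

#' Mean squared error
#'
#' `sum((y - y_hat)^2) / n`, the cost minimized during LSTM training and
#' used as the optimizer fitness.
#'
#' @param y,y_hat Equal-length numeric vectors.
#' @return Non-negative scalar; zero iff the vectors are identical.
#' @examples
#' mse(c(0, 0, 0), c(1, 2, 3))  # 14/3
#' @export
mse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  if (length(y) < 1L) stop("mse needs at least one observation")
  mean((y - y_hat)^2)
}

#' Loss and gradients of a batch
#'
#' Evaluates the mean-squared-error loss of `params` on a batch and, if
#' requested, its exact gradients by backpropagation through time.
#'
#' @param params An `lstm_params` object.
#' @param x Input matrix/array (see [lstm_forward()]).
#' @param y Targets: length-`T` vector or `T x B` matrix matching `x`.
#' @param grad Compute gradients as well?
#' @return A list with `loss`, `preds`, and (if `grad`) `dW`, `dB`
#'   (per-layer lists), `dwy`, `dby`.
#' @export
lstm_loss <- function(params, x, y, grad = FALSE) {
  cube <- as_input_cube(x, params$n_input)
  Y <- if (is.matrix(y)) y else matrix(y, ncol = 1L)
  if (nrow(Y) != dim(cube)[3] || ncol(Y) != dim(cube)[2]) {
    stop("target shape does not match input batch")
  }
  lstm_pass_cpp(lapply(params$layers, `[[`, "W"),
                lapply(params$layers, `[[`, "B"),
                params$w_y, params$b_y, cube, Y, grad)
}

#' LSTM training configuration
#'
#' @param epochs Number of passes over the training breaths (N_I).
#' @param learning_rate Step size (L_R).
#' @param hidden_units Hidden units per layer (N_HU).
#' @param layers Number of stacked layers (N_L).
#' @param batch_size Breaths per gradient update (whole breaths are the
#'   batching unit).
#' @param weight_optimizer `"adam"` (default) or `"sgd"`.
#' @param seed Integer seed controlling initialization and batch order.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 20L, learning_rate = 1e-2,
                         hidden_units = 16L, layers = 1L,
                         batch_size = 32L,
                         weight_optimizer = c("adam", "sgd"), seed = 1L) {
  weight_optimizer <- match.arg(weight_optimizer)
  stopifnot(epochs >= 1, learning_rate >= 0, hidden_units >= 1,
            layers >= 1, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 hidden_units = as.integer(hidden_units),
                 layers = as.integer(layers),
                 batch_size = as.integer(batch_size),
                 weight_optimizer = weight_optimizer,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Flatten parameters to a named list of arrays (for Adam state bookkeeping).
params_arrays <- function(params) {
  out <- list()
  for (l in seq_along(params$layers)) {
    out[[paste0("W", l)]] <- params$layers[[l]]$W
    out[[paste0("B", l)]] <- params$layers[[l]]$B
  }
  out$w_y <- params$w_y
  out$b_y <- params$b_y
  out
}

grad_arrays <- function(gr, n_layers) {
  out <- list()
  for (l in seq_len(n_layers)) {
    out[[paste0("W", l)]] <- gr$dW[[l]]
    out[[paste0("B", l)]] <- drop(gr$dB[[l]])
    dim(out[[paste0("B", l)]]) <- NULL
  }
  out$w_y <- drop(gr$dwy)
  out$b_y <- gr$dby
  out
}

arrays_to_params <- function(arr, params) {
  for (l in seq_along(params$layers)) {
    params$layers[[l]]$W <- arr[[paste0("W", l)]]
    params$layers[[l]]$B <- as.numeric(arr[[paste0("B", l)]])
  }
  params$w_y <- as.numeric(arr$w_y)
  params$b_y <- as.numeric(arr$b_y)
  params
}

# Pack a list of I x T matrices (equal T) into an I x B x T cube plus a
# T x B target matrix.
pack_batch <- function(x_list, y_list) {
  I <- nrow(x_list[[1]]); T_len <- ncol(x_list[[1]]); B <- length(x_list)
  cube <- array(0, dim = c(I, B, T_len))
  Y <- matrix(0, nrow = T_len, ncol = B)
  for (b in seq_len(B)) {
    cube[, b, ] <- x_list[[b]]
    Y[, b] <- y_list[[b]]
  }
  list(x = cube, y = Y)
}

#' Train an LSTM regressor by mini-batch gradient descent
#'
#' Minimizes the mean squared error over all time steps of all sequences.
#' Sequences (whole breaths) are the batching unit; within an epoch they
#' are shuffled, grouped by length, and split into batches of at most
#' `batch_size`.  Gradients come from exact backpropagation through time;
#' updates use Adam (default) or plain SGD.
#'
#' @param x List of `n_input x T` input matrices, one per sequence.
#' @param y List of length-`T` target vectors matching `x`.
#' @param config A [train_config()].
#' @param params Optional warm-start `lstm_params`; by default parameters
#'   are freshly initialized from `config$seed`.
#' @return A list with the trained `params` and the per-epoch `loss_trace`:
#'   entry `e` is the cell-weighted mean of the batch losses evaluated
#'   during epoch `e` (each before its own update), the usual running
#'   training loss.
#' @export
lstm_train <- function(x, y, config = train_config(), params = NULL) {
  if (length(x) < 1L) stop("training set must be non-empty")
  if (length(x) != length(y)) stop("x and y must have the same length")
  set.seed(config$seed)
  n_input <- nrow(x[[1]])
  if (is.null(params)) {
    params <- lstm_init_params(n_input, config$hidden_units, config$layers)
  }
  lr <- config$learning_rate
  adam <- config$weight_optimizer == "adam"
  if (adam) {
    m_state <- lapply(params_arrays(params), function(a) a * 0)
    v_state <- m_state
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
  }

  lens <- vapply(x, ncol, 1L)
  loss_trace <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    epoch_sse <- 0; epoch_cells <- 0
    ord <- sample.int(length(x))
    for (grp in split(ord, lens[ord])) {
      batches <- split(grp, ceiling(seq_along(grp) / config$batch_size))
      for (bt in batches) {
        pk <- pack_batch(x[bt], y[bt])
        out <- lstm_loss(params, pk$x, pk$y, grad = TRUE)
        if (!is.finite(out$loss)) {
          stop(sprintf(
            "training diverged at epoch %d (learning_rate = %g)",
            epoch, lr))
        }
        epoch_sse <- epoch_sse + out$loss * length(pk$y)
        epoch_cells <- epoch_cells + length(pk$y)
        if (lr == 0) next
        gr <- grad_arrays(out, config$layers)
        arr <- params_arrays(params)
        if (adam) {
          step <- step + 1L
          for (nm in names(arr)) {
            m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * gr[[nm]]
            v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * gr[[nm]]^2
            mhat <- m_state[[nm]] / (1 - beta1^step)
            vhat <- v_state[[nm]] / (1 - beta2^step)
            arr[[nm]] <- arr[[nm]] - lr * mhat / (sqrt(vhat) + eps)
          }
        } else {
          for (nm in names(arr)) arr[[nm]] <- arr[[nm]] - lr * gr[[nm]]
        }
        params <- arrays_to_params(arr, params)
      }
    }
    loss_trace[epoch] <- epoch_sse / epoch_cells
  }
  list(params = params, loss_trace = loss_trace)
}
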