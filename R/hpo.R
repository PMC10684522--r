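#' Hyperparameter search space for the LSTM
#'
#' Maps a point of the optimizer's unit box `[0, 1]^4` to an LSTM
#' training configuration.  Integer dimensions (epochs N_I, hidden units
#' N_HU, layers N_L) decode by round-half-up after an affine map; the
#' learning rate L_R decodes exponentially (uniform in log space).
#'
#' @param n_iter Range of training epochs N_I (default `c(5, 50)`).
#' @param learning_rate Range of L_R (default `c(1e-4, 1e-1)`),
#'   log-scaled.
#' @param hidden_units Range of N_HU (default `c(4, 128)`).
#' @param layers Range of N_L (default `c(1, 3)`).
#' @return A list of class `hyperparam_space` with a `space` field (the
#'   unit [search_space()] the optimizer sees).
#' @export
hyperparam_space <- function(n_iter = c(5, 50),
                             learning_rate = c(1e-4, 1e-1),
                             hidden_units = c(4, 128),
                             layers = c(1, 3)) {
  stopifnot(length(n_iter) == 2, length(learning_rate) == 2,
            length(hidden_units) == 2, length(layers) == 2,
            all(learning_rate > 0),
            n_iter[1] <= n_iter[2], learning_rate[1] <= learning_rate[2],
            hidden_units[1] <= hidden_units[2], layers[1] <= layers[2])
  structure(list(n_iter = n_iter, learning_rate = learning_rate,
                 hidden_units = hidden_units, layers = layers,
                 space = search_space(rep(0, 4), rep(1, 4))),
            class = "hyperparam_space")
}

round_half_up <- function(x) floor(x + 0.5)

#' Decode an optimizer position into a training configuration
#'
#' Out-of-bounds coordinates are clamped to the unit box before decoding,
#' so decoding never fails.  `decode_position(encode_config(cfg))`
#' recovers `cfg` for representable hyperparameter values.
#'
#' @param pos Numeric vector of length 4 (coordinates for N_I, L_R,
#'   N_HU, N_L).
#' @param hspace A [hyperparam_space()].
#' @param base A [train_config()] supplying the non-searched fields
#'   (batch size, weight optimizer, seed).
#' @return A [train_config()].
#' @examples
#' hs <- hyperparam_space()
#' decode_position(c(0, 0, 0, 0), hs)  # lower corner: N_I=5, L_R=1e-4, ...
#' @export
decode_position <- function(pos, hspace, base = train_config()) {
  if (length(pos) != 4L) stop("position must have four coordinates")
  p <- pmin(pmax(pos, 0), 1)
  dec_int <- function(u, rng) {
    as.integer(min(max(round_half_up(rng[1] + u * (rng[2] - rng[1])),
                       rng[1]), rng[2]))
  }
  lr <- exp(log(hspace$learning_rate[1]) +
              p[2] * (log(hspace$learning_rate[2]) -
                        log(hspace$learning_rate[1])))
  train_config(epochs = dec_int(p[1], hspace$n_iter),
               learning_rate = lr,
               hidden_units = dec_int(p[3], hspace$hidden_units),
               layers = dec_int(p[4], hspace$layers),
               batch_size = base$batch_size,
               weight_optimizer = base$weight_optimizer,
               seed = base$seed)
}

#' Encode a training configuration as an optimizer position
#'
#' @param config A [train_config()].
#' @param hspace A [hyperparam_space()].
#' @return A numeric vector of length 4 in the unit box.
#' @export
encode_config <- function(config, hspace) {
  enc_int <- function(v, rng) (v - rng[1]) / (rng[2] - rng[1])
  c(enc_int(config$epochs, hspace$n_iter),
    (log(config$learning_rate) - log(hspace$learning_rate[1])) /
      (log(hspace$learning_rate[2]) - log(hspace$learning_rate[1])),
    enc_int(config$hidden_units, hspace$hidden_units),
    enc_int(config$layers, hspace$layers))
}

#' Split a ventilator table into training and test sets by breath
#'
#' Whole breaths never straddle the split.
#'
#' @param table Schema data.frame with a `breath_id` column.
#' @param train_frac Fraction of breaths assigned to training
#'   (default 0.8).
#' @param seed Integer seed for the breath shuffle.
#' @return A list with data.frames `train` and `test`.
#' @export
split_data <- function(table, train_frac = 0.8, seed = 1L) {
  ids <- unique(table$breath_id)
  if (length(ids) < 2L) stop("need at least two breaths to split")
  set.seed(seed)
  n_train <- round_half_up(train_frac * length(ids))
  n_train <- min(max(n_train, 1L), length(ids) - 1L)
  train_ids <- sort(sample(ids, n_train))
  list(train = table[table$breath_id %in% train_ids, , drop = FALSE],
       test = table[!(table$breath_id %in% train_ids), , drop = FALSE])
}

# Breath-level k-fold assignment: returns a fold label per unique breath id.
breath_folds <- function(ids, k, seed) {
  set.seed(seed)
  folds <- rep_len(seq_len(k), length(ids))
  sample(folds)
}

#' Fitness of a hyperparameter configuration
#'
#' Trains the LSTM pipeline and returns a mean-squared-error score.  Mode
#' `"train_mse"` trains on all of `data` and scores on the same data (the
#' cost driving the tuning loop); `"cv5"` returns the mean held-out-fold
#' MSE over five breath-level folds, which guards against degenerate
#' overfit selections.  A diverging training run scores `+Inf` so the
#' surrounding metaheuristic can keep exploring.
#'
#' @param config A [train_config()].
#' @param data Training table in the ventilator schema.
#' @param mode `"train_mse"` or `"cv5"`.
#' @param seed Integer seed; fitness is deterministic given
#'   `(config, data, mode, seed)`.
#' @return Non-negative scalar MSE (possibly `Inf`).
#' @export
lstm_fitness <- function(config, data, mode = c("train_mse", "cv5"),
                         seed = 1L) {
  mode <- match.arg(mode)
  config$seed <- as.integer(seed)
  if (mode == "train_mse") {
    val <- tryCatch({
      model <- vent_lstm(data, config)
      mse(data$pressure, predict(model, data))
    }, error = function(e) Inf)
    return(val)
  }
  ids <- unique(data$breath_id)
  if (length(ids) < 5L) stop("cv5 needs at least five breaths")
  fold <- breath_folds(ids, 5L, seed)
  fold_mse <- numeric(5L)
  for (f in 1:5) {
    hold <- ids[fold == f]
    tr <- data[!(data$breath_id %in% hold), , drop = FALSE]
    te <- data[data$breath_id %in% hold, , drop = FALSE]
    fold_mse[f] <- tryCatch({
      model <- vent_lstm(tr, config)
      mse(te$pressure, predict(model, te))
    }, error = function(e) Inf)
  }
  mean(fold_mse)
}

#' Tune LSTM hyperparameters with a metaheuristic
#'
#' The tuning loop: optimizer positions in the unit box decode to
#' `(N_I, L_R, N_HU, N_L)` configurations, each scored by [lstm_fitness()]
#' on the training data; after the search the final model is retrained on
#' the full training split with the best configuration.  Decoded
#' configurations are cached, so re-visiting the same integer-rounded
#' point does not retrain.
#'
#' @param data Training table in the ventilator schema.
#' @param method Optimizer: `"choa"`, `"pso"`, `"gwo"` or `"woa"`.
#' @param hspace A [hyperparam_space()].
#' @param opt_config Optimizer settings (defaults to
#'   [optimizer_defaults()] for `method`).
#' @param seed Root seed for the whole tuning run.
#' @param fitness_mode `"cv5"` (default, recommended) or `"train_mse"`.
#' @param base A [train_config()] supplying non-searched fields.
#' @return A list of class `tuning_result`: `best_config`,
#'   `best_position`, `best_fitness`, `trace` (best-so-far fitness per
#'   iteration), `eval_log` (one row per objective evaluation: decoded
#'   hyperparameters, fitness, wall time), `final_model` (a `vent_lstm`),
#'   `method`, `seed`, `n_evals`.
#' @export
tune_lstm <- function(data, method = c("choa", "pso", "gwo", "woa"),
                      hspace = hyperparam_space(), opt_config = NULL,
                      seed = 1L, fitness_mode = c("cv5", "train_mse"),
                      base = train_config()) {
  method <- match.arg(method)
  fitness_mode <- match.arg(fitness_mode)
  if (is.null(opt_config)) opt_config <- optimizer_defaults(method)

  log_env <- new.env(parent = emptyenv())
  log_env$rows <- list()
  cache <- new.env(parent = emptyenv())

  objective <- function(pos) {
    cfg <- decode_position(pos, hspace, base)
    key <- sprintf("%d|%.12g|%d|%d", cfg$epochs, cfg$learning_rate,
                   cfg$hidden_units, cfg$layers)
    if (!is.null(cache[[key]])) {
      fit <- cache[[key]]
      elapsed <- 0
    } else {
      t0 <- proc.time()[["elapsed"]]
      fit <- lstm_fitness(cfg, data, fitness_mode, seed = seed)
      elapsed <- proc.time()[["elapsed"]] - t0
      cache[[key]] <- fit
    }
    log_env$rows[[length(log_env$rows) + 1L]] <- data.frame(
      n_iter = cfg$epochs, learning_rate = cfg$learning_rate,
      hidden_units = cfg$hidden_units, layers = cfg$layers,
      fitness = fit, wall_time = elapsed)
    # +Inf sentinels stay out of the optimizer's arithmetic
    if (!is.finite(fit)) 1e12 else fit
  }

  res <- run_optimizer(objective, hspace$space, method, opt_config, seed)
  eval_log <- do.call(rbind, log_env$rows)
  if (all(!is.finite(eval_log$fitness))) {
    stop("every evaluation diverged; narrow the learning-rate bounds")
  }
  best_row <- which.min(eval_log$fitness)
  best_config <- decode_position(res$best_position, hspace, base)
  best_config$seed <- as.integer(seed)
  final_model <- vent_lstm(data, best_config)
  structure(list(best_config = best_config,
                 best_position = res$best_position,
                 best_fitness = eval_log$fitness[best_row],
                 trace = res$trace, eval_log = eval_log,
                 final_model = final_model, method = method,
                 seed = seed, n_evals = res$n_evals,
                 fitness_mode = fitness_mode),
            class = "tuning_result")
}
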