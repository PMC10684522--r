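ventilator_schema <- function() {
  c("id", "breath_id", "R", "C", "time_step", "u_in", "u_out", "pressure")
}

#' Read a ventilator CSV
#'
#' Reads a table in the public ventilator-pressure dialect (header
#' `id,breath_id,R,C,time_step,u_in,u_out,pressure`, comma separated, dot
#' decimal, no index column) and validates the per-breath invariants:
#' strictly increasing time, `u_in` in `[0, 100]`, binary `u_out`, finite
#' pressure.  Row order within each breath is preserved.
#'
#' @param path Path to the CSV file.
#' @return A data.frame in the schema.
#' @export
read_ventilator_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          data.table = FALSE)
  expected <- ventilator_schema()
  if (!identical(names(dt), expected)) {
    stop("unexpected header; expected columns: ",
         paste(expected, collapse = ","),
         " but found: ", paste(names(dt), collapse = ","))
  }
  validate_breaths(dt)
  dt
}

validate_breaths <- function(table) {
  for (bid in unique(table$breath_id)) {
    rows <- table[table$breath_id == bid, , drop = FALSE]
    if (any(diff(rows$time_step) <= 0)) {
      stop("non-monotone time within breath_id ", bid)
    }
    if (any(rows$u_in < 0 | rows$u_in > 100)) {
      stop("u_in outside [0, 100] in breath_id ", bid)
    }
    if (!all(rows$u_out %in% c(0, 1))) {
      stop("u_out must be binary in breath_id ", bid)
    }
    if (any(!is.finite(rows$pressure))) {
      stop("non-finite pressure in breath_id ", bid)
    }
  }
  invisible(table)
}

fmt_num <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15,
         sprintf("%d", as.integer(round(x))),
         sprintf("%.17g", x))
}

#' Write a ventilator CSV
#'
#' Round-trip-safe writer (17 significant digits for non-integer values).
#'
#' @param table Data.frame in the ventilator schema.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ventilator_csv <- function(table, path) {
  expected <- ventilator_schema()
  miss <- setdiff(expected, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  write_csv17(table[expected], path)
  invisible(path)
}

# Generic deterministic CSV writer with round-trip-safe numerics.
write_csv17 <- function(table, path) {
  cols <- lapply(table, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  })
  lines <- c(paste(names(table), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

# Deterministic polynomial fingerprint of a configuration object,
# reported as 8 hex characters; used to stamp artifacts with the
# configuration that produced them.
config_hash <- function(obj) {
  s <- paste(utils::capture.output(utils::str(obj, digits.d = 15)),
             collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_json_artifact <- function(x, path) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Save a trained model checkpoint
#'
#' Serializes a [vent_lstm()] model as a flat named-array archive
#' (`<path>.params.csv`: columns `name,i,j,value`, one row per entry,
#' 17-significant-digit values) plus a JSON sidecar (`<path>.json`) of
#' the hyperparameters, feature scaling, seed and config hash.
#'
#' @param model A `vent_lstm` model.
#' @param path Path prefix (two files are written).
#' @return The prefix, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "vent_lstm"))
  arr <- params_arrays(model$params)
  rows <- lapply(names(arr), function(nm) {
    a <- arr[[nm]]
    if (is.matrix(a)) {
      data.frame(name = nm,
                 i = rep(seq_len(nrow(a)), times = ncol(a)),
                 j = rep(seq_len(ncol(a)), each = nrow(a)),
                 value = as.vector(a))
    } else {
      data.frame(name = nm, i = seq_along(a), j = 1L, value = as.numeric(a))
    }
  })
  tab <- do.call(rbind, rows)
  write_csv17(tab, paste0(path, ".params.csv"))
  side <- list(
    n_input = model$params$n_input,
    n_hidden = model$params$n_hidden,
    n_layers = model$params$n_layers,
    feature_cols = model$feature_cols,
    center = as.list(stats::setNames(as.numeric(model$center),
                                     names(model$center))),
    scale = as.list(stats::setNames(as.numeric(model$scale),
                                    names(model$scale))),
    y_center = model$y_center,
    y_scale = model$y_scale,
    config = unclass(model$config),
    seed = model$seed,
    loss_trace = model$loss_trace,
    config_hash = config_hash(unclass(model$config)))
  write_json_artifact(side, paste0(path, ".json"))
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Prefix used with [save_checkpoint()].
#' @return A `vent_lstm` model whose predictions reproduce the saved
#'   model's exactly.
#' @export
load_checkpoint <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- data.table::fread(paste0(path, ".params.csv"), data.table = FALSE)
  H <- side$n_hidden; L <- side$n_layers; I <- side$n_input
  params <- structure(list(layers = vector("list", L),
                           w_y = NULL, b_y = NULL,
                           n_input = as.integer(I),
                           n_hidden = as.integer(H),
                           n_layers = as.integer(L)),
                      class = "lstm_params")
  for (l in seq_len(L)) {
    Il <- if (l == 1L) I else H
    sub <- tab[tab$name == paste0("W", l), ]
    W <- matrix(0, nrow = 4 * H, ncol = H + Il)
    W[cbind(sub$i, sub$j)] <- sub$value
    Bsub <- tab[tab$name == paste0("B", l), ]
    B <- numeric(4 * H); B[Bsub$i] <- Bsub$value
    params$layers[[l]] <- list(W = W, B = B)
  }
  wsub <- tab[tab$name == "w_y", ]
  w_y <- numeric(H); w_y[wsub$i] <- wsub$value
  params$w_y <- w_y
  params$b_y <- tab$value[tab$name == "b_y"]
  cfg <- side$config
  config <- train_config(epochs = cfg$epochs,
                         learning_rate = cfg$learning_rate,
                         hidden_units = cfg$hidden_units,
                         layers = cfg$layers, batch_size = cfg$batch_size,
                         weight_optimizer = cfg$weight_optimizer,
                         seed = cfg$seed)
  structure(list(params = params, config = config,
                 feature_cols = side$feature_cols,
                 center = unlist(side$center), scale = unlist(side$scale),
                 y_center = side$y_center, y_scale = side$y_scale,
                 loss_trace = side$loss_trace, seed = side$seed),
            class = "vent_lstm")
}

run_config_keys <- function() {
  list(
    seed = "integer",
    optimizer = c("method", "population", "max_iter", "runs", "prey_prob",
                  "l0", "a_formula", "chaotic_map", "map_init",
                  "c1", "c2", "w_max", "w_min", "spiral_b"),
    hyperparameters = c("n_iter", "learning_rate", "hidden_units", "layers"),
    training = c("batch_size", "weight_optimizer", "epochs", "learning_rate",
                 "hidden_units", "layers"),
    simulator = c("n_breaths", "peep", "leak_frac", "noise_sd", "q_max",
                  "n_steps", "total_time"),
    fitness_mode = "character",
    verbosity = "integer")
}

#' Read a run configuration file
#'
#' YAML file with blocks `optimizer`, `hyperparameters`, `training`,
#' `simulator` and scalar keys `seed`, `fitness_mode`, `verbosity`.
#' Unknown keys (top-level or within a block) are rejected with a message
#' naming them.
#'
#' @param path Path to the YAML file.
#' @return A named list of configuration blocks.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- run_config_keys()
  unknown <- setdiff(names(cfg), names(known))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         "; known keys: ", paste(names(known), collapse = ", "))
  }
  for (block in c("optimizer", "hyperparameters", "training", "simulator")) {
    if (!is.null(cfg[[block]])) {
      bad <- setdiff(names(cfg[[block]]), known[[block]])
      if (length(bad)) {
        stop("unknown key(s) in block '", block, "': ",
             paste(bad, collapse = ", "))
      }
    }
  }
  cfg
}
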