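default_feature_cols <- function() {
  c("time_step", "u_in", "u_out", "R", "C", "delta", "cisv", "integral")
}

# Split a schema table into per-breath (features, target) pairs in order
# of first appearance of each breath_id.
breath_matrices <- function(table, feature_cols, center = NULL, scale = NULL,
                            target = "pressure") {
  ids <- unique(table$breath_id)
  x <- vector("list", length(ids))
  y <- vector("list", length(ids))
  feat <- as.matrix(table[feature_cols])
  if (!is.null(center)) {
    feat <- sweep(sweep(feat, 2, center, "-"), 2, scale, "/")
  }
  idx_by_id <- split(seq_len(nrow(table)), factor(table$breath_id, levels = ids))
  for (b in seq_along(ids)) {
    rows <- idx_by_id[[b]]
    x[[b]] <- t(feat[rows, , drop = FALSE])
    y[[b]] <- if (target %in% names(table)) table[[target]][rows] else NULL
  }
  list(ids = ids, x = x, y = y)
}

#' Fit the full LSTM pressure-prediction pipeline
#'
#' Takes a table in the ventilator schema, engineers and selects the
#' respiratory-circuit features, standardizes them (z-scores computed on
#' the supplied data, i.e. the training split), and trains the LSTM
#' regressor.  The pressure target is z-scored with the same training
#' statistics for conditioning; predictions are mapped back to cmH2O.
#'
#' @param data Data.frame with columns `breath_id`, `R`, `C`,
#'   `time_step`, `u_in`, `u_out`, `pressure`.
#' @param config A [train_config()].
#' @param feature_cols Feature columns fed to the network; defaults to
#'   `time_step, u_in, u_out, R, C, delta, cisv, integral`.
#' @return An object of class `vent_lstm` holding the trained
#'   parameters, the training configuration, the feature scaling and the
#'   per-epoch loss trace.  Use [predict.vent_lstm()] for new breaths.
#' @export
vent_lstm <- function(data, config = train_config(),
                      feature_cols = default_feature_cols()) {
  feats <- select_features(extract_features(data))
  missing_cols <- setdiff(feature_cols, names(feats))
  if (length(missing_cols)) {
    stop("feature column(s) not available: ",
         paste(missing_cols, collapse = ", "))
  }
  fm <- as.matrix(feats[feature_cols])
  center <- colMeans(fm)
  scale <- apply(fm, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  y_center <- mean(feats$pressure)
  y_scale <- stats::sd(feats$pressure)
  if (y_scale == 0 || !is.finite(y_scale)) y_scale <- 1
  bm <- breath_matrices(feats, feature_cols, center, scale)
  y_scaled <- lapply(bm$y, function(v) (v - y_center) / y_scale)
  fit <- lstm_train(bm$x, y_scaled, config)
  structure(list(params = fit$params, config = config,
                 feature_cols = feature_cols,
                 center = center, scale = scale,
                 y_center = y_center, y_scale = y_scale,
                 loss_trace = fit$loss_trace, seed = config$seed),
            class = "vent_lstm")
}

#' Predict airway pressure for new breaths
#'
#' @param object A fitted [vent_lstm()] model.
#' @param newdata Data.frame in the ventilator schema (the `pressure`
#'   column is not required).
#' @param ... Unused.
#' @return Numeric vector of predicted pressures, one per row of
#'   `newdata`, in row order.
#' @export
predict.vent_lstm <- function(object, newdata, ...) {
  feats <- select_features(extract_features(newdata))
  bm <- breath_matrices(feats, object$feature_cols,
                        object$center, object$scale)
  preds <- lapply(bm$x, function(xb) lstm_forward(object$params, xb))
  unlist(preds, use.names = FALSE) * object$y_scale + object$y_center
}
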