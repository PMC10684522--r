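#' One-way analysis of variance
#'
#' Classical equal-variance F test for equality of group means, used at a
#' 95 % confidence level to decide whether repeated tuning runs of
#' different optimizers differ significantly.
#'
#' @param groups List of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @return A list with the `F` statistic, the upper-tail `p` value, and
#'   the degrees of freedom `df1`, `df2`.  If every group is constant and
#'   all means coincide the statistic is undefined: `F` and `p` are `NA`
#'   and a warning is raised.
#' @examples
#' anova_oneway(list(c(1, 2), c(3, 4), c(5, 6)))$F  # 16
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups")
  }
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("every group needs at least two values")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  k <- length(groups); n <- length(y)
  within_ss <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1))
  between_ss <- sum(vapply(groups, function(v) {
    length(v) * (mean(v) - mean(y))^2
  }, 1))
  if (within_ss == 0 && between_ss == 0) {
    warning("F statistic undefined: no variance within or between groups")
    return(list(F = NA_real_, p = NA_real_, df1 = k - 1L, df2 = n - k))
  }
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ow$statistic), p = unname(ow$p.value),
       df1 = unname(ow$parameter[1]), df2 = unname(ow$parameter[2]))
}

#' K-nearest-neighbour regression
#'
#' Reference baseline regressor: predictions are the mean target of the
#' `k` nearest training rows by Euclidean distance on standardized
#' features.  Ties in distance are broken by training-row index, so
#' predictions are deterministic.
#'
#' @param train_x Numeric matrix/data.frame of training features.
#' @param train_y Numeric target vector.
#' @param query_x Rows to predict for (same columns as `train_x`).
#' @param k Number of neighbours (default 5, `1 <= k <= nrow(train_x)`).
#' @param standardize Z-score the features using training statistics
#'   (default `TRUE`).
#' @return Numeric vector of predictions, one per query row.
#' @export
knn_regress <- function(train_x, train_y, query_x, k = 5L,
                        standardize = TRUE) {
  train_x <- as.matrix(train_x); query_x <- as.matrix(query_x)
  n <- nrow(train_x)
  if (k < 1L) stop("k must be at least 1")
  if (k > n) stop("k cannot exceed the number of training rows")
  if (length(train_y) != n) stop("train_y length must match train_x rows")
  if (standardize) {
    ctr <- colMeans(train_x)
    scl <- apply(train_x, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    train_x <- sweep(sweep(train_x, 2, ctr, "-"), 2, scl, "/")
    query_x <- sweep(sweep(query_x, 2, ctr, "-"), 2, scl, "/")
  }
  apply(query_x, 1, function(q) {
    d2 <- colSums((t(train_x) - q)^2)
    nn <- order(d2, seq_len(n))[seq_len(k)]
    mean(train_y[nn])
  })
}

#' Exhaustive grid search by cross-validated MSE
#'
#' Evaluates every combination of the supplied hyperparameter grid with
#' breath-level k-fold cross-validation and returns the best setting;
#' ties are broken by grid order (first win).
#'
#' @param fit_predict Function `(train_df, test_df, params)` returning
#'   predictions for the rows of `test_df`; `params` is one named list of
#'   hyperparameter values.
#' @param grid Named list of candidate value vectors; the Cartesian
#'   product is searched in [expand.grid()] order.
#' @param data Table in the ventilator schema (folds are formed at
#'   `breath_id` level).
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return A list with `best` (named list of the winning setting),
#'   `best_mse`, and `results` (a data.frame of all settings and their
#'   CV MSE), plus `n_evaluations = nrow(results) * folds`.
#' @export
grid_search <- function(fit_predict, grid, data, folds = 5L, seed = 1L) {
  if (!length(grid)) stop("grid must be non-empty")
  settings <- expand.grid(grid, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
  ids <- unique(data$breath_id)
  if (length(ids) < folds) stop("need at least as many breaths as folds")
  fold <- breath_folds(ids, folds, seed)
  cv_mse <- numeric(nrow(settings))
  for (s in seq_len(nrow(settings))) {
    params <- as.list(settings[s, , drop = FALSE])
    errs <- numeric(folds)
    for (f in seq_len(folds)) {
      hold <- ids[fold == f]
      tr <- data[!(data$breath_id %in% hold), , drop = FALSE]
      te <- data[data$breath_id %in% hold, , drop = FALSE]
      preds <- fit_predict(tr, te, params)
      errs[f] <- mse(te$pressure, preds)
    }
    cv_mse[s] <- mean(errs)
  }
  best <- which.min(cv_mse)  # which.min takes the first minimum: grid order
  list(best = as.list(settings[best, , drop = FALSE]),
       best_mse = cv_mse[best],
       results = cbind(settings, cv_mse = cv_mse),
       n_evaluations = nrow(settings) * folds)
}

#' Multi-run statistical comparison of optimizers
#'
#' Repeats the whole tuning pipeline `n_runs` times per optimizer on the
#' same train/test split (seeds `base_seed + 1 .. base_seed + n_runs`),
#' records each run's test MSE in a run-by-method matrix, and applies a
#' one-way ANOVA across the methods' columns at a 95 % confidence level,
#' plus pairwise two-group ANOVAs against the first method.
#'
#' @param data Table in the ventilator schema.
#' @param methods Character vector of optimizers to compare.
#' @param n_runs Independent repetitions per method (>= 2; the reference
#'   protocol uses 10).
#' @param hspace A [hyperparam_space()].
#' @param opt_configs Optional named list of optimizer settings per
#'   method (defaults per method otherwise).
#' @param base_seed Root seed.
#' @param fitness_mode Passed to [tune_lstm()].
#' @param base A [train_config()] with non-searched fields.
#' @param train_frac Train share of the breath-level split.
#' @return A list of class `optimizer_comparison`: `run_matrix`
#'   (`n_runs x length(methods)` test MSEs), `summary` (per-method mean
#'   and sd, best method = argmin of column means), `anova` (overall F
#'   and p), `pairwise` (p-values of the first method against each
#'   other), `failed` (failed runs, excluded, matrix marked incomplete
#'   via `complete = FALSE`).
#' @export
compare_optimizers <- function(data, methods = c("choa", "pso", "gwo", "woa"),
                               n_runs = 10L, hspace = hyperparam_space(),
                               opt_configs = NULL, base_seed = 1L,
                               fitness_mode = c("cv5", "train_mse"),
                               base = train_config(), train_frac = 0.8) {
  fitness_mode <- match.arg(fitness_mode)
  if (n_runs < 2L) stop("n_runs must be at least 2")
  sp <- split_data(data, train_frac, seed = base_seed)
  run_matrix <- matrix(NA_real_, nrow = n_runs, ncol = length(methods),
                       dimnames = list(NULL, methods))
  failed <- list()
  for (m in seq_along(methods)) {
    cfg <- if (!is.null(opt_configs)) opt_configs[[methods[m]]] else NULL
    for (r in seq_len(n_runs)) {
      seed_r <- base_seed + r
      out <- tryCatch({
        tr <- tune_lstm(sp$train, methods[m], hspace, cfg, seed = seed_r,
                        fitness_mode = fitness_mode, base = base)
        mse(sp$test$pressure, predict(tr$final_model, sp$test))
      }, error = function(e) e)
      if (inherits(out, "error")) {
        failed[[length(failed) + 1L]] <- list(method = methods[m],
                                              run = r,
                                              message = conditionMessage(out))
      } else {
        run_matrix[r, m] <- out
      }
    }
  }
  complete <- !anyNA(run_matrix)
  cols <- lapply(seq_along(methods), function(m) {
    v <- run_matrix[, m]
    v[is.finite(v)]
  })
  names(cols) <- methods
  anova_res <- if (all(vapply(cols, length, 1L) >= 2L)) {
    anova_oneway(cols)
  } else {
    list(F = NA_real_, p = NA_real_)
  }
  pairwise <- if (length(methods) > 1L) {
    vapply(2:length(methods), function(m) {
      if (length(cols[[1]]) >= 2L && length(cols[[m]]) >= 2L) {
        anova_oneway(cols[c(1L, m)])$p
      } else NA_real_
    }, 1)
  } else numeric(0)
  if (length(pairwise)) names(pairwise) <- methods[-1]
  means <- colMeans(run_matrix, na.rm = TRUE)
  summary_df <- data.frame(method = methods, mean_mse = means,
                           sd_mse = apply(run_matrix, 2, stats::sd,
                                          na.rm = TRUE),
                           row.names = NULL)
  structure(list(run_matrix = run_matrix, summary = summary_df,
                 best_method = methods[which.min(means)],
                 anova = anova_res, pairwise = pairwise,
                 failed = failed, complete = complete,
                 n_runs = n_runs, base_seed = base_seed),
            class = "optimizer_comparison")
}
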