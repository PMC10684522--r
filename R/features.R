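#' Spearman's rank correlation
#'
#' Computed from the rank-difference formula
#' `rho = 1 - 6 * sum(d_i^2) / (n * (n^2 - 1))`, with average ranks
#' assigned to ties.
#'
#' @param x,y Equal-length numeric vectors, `n >= 2`, each with non-zero
#'   variance.
#' @return A scalar in `[-1, 1]`; symmetric in its arguments and
#'   invariant under strictly monotone transforms of either one.
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))  # 0.8
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L) stop("spearman_rho needs at least two observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("spearman_rho is undefined for a constant vector")
  }
  d <- rank(x, ties.method = "average") - rank(y, ties.method = "average")
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

#' Correlation matrix of a feature table
#'
#' Pairwise correlations among all numeric columns, Spearman by default
#' (Pearson available).  Constant columns are flagged: their off-diagonal
#' entries are `NA` and a warning names them; the diagonal stays 1.
#'
#' @param table A data.frame.
#' @param method `"spearman"` or `"pearson"`.
#' @return A symmetric matrix with unit diagonal and entries in `[-1, 1]`
#'   (or `NA` where undefined).
#' @export
correlation_matrix <- function(table, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  num <- table[vapply(table, is.numeric, TRUE)]
  if (ncol(num) < 2L) stop("need at least two numeric columns")
  m <- as.matrix(num)
  constant <- apply(m, 2, function(col) stats::var(col) == 0)
  if (any(constant)) {
    warning("constant column(s) have undefined correlations: ",
            paste(colnames(m)[constant], collapse = ", "))
  }
  if (method == "spearman") {
    r <- apply(m, 2, rank, ties.method = "average")
    n <- nrow(m)
    p <- ncol(m)
    out <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
    for (j in seq_len(p)) {
      for (k in j:p) {
        if (constant[j] || constant[k]) next
        d <- r[, j] - r[, k]
        out[j, k] <- out[k, j] <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))
      }
    }
  } else {
    out <- suppressWarnings(stats::cor(m, method = "pearson"))
    out[constant, ] <- NA_real_
    out[, constant] <- NA_real_
  }
  diag(out) <- 1
  out
}

#' Engineered respiratory-circuit features
#'
#' Appends the four engineered features to a ventilator table, computed
#' within each breath (features never leak across `breath_id`
#' boundaries):
#' * `delta` — the lung setting `R * C`, constant within a breath;
#' * `cisv` — cumulative sum of the inspiratory-valve opening `u_in`;
#' * `integral` — inter-sample time difference (0 at the first sample);
#' * `differential` — inter-sample `u_in` difference (0 at the first
#'   sample).
#'
#' @param table A data.frame with at least `breath_id`, `R`, `C`,
#'   `time_step`, `u_in`.
#' @return The table with the four feature columns appended; row order
#'   preserved.
#' @examples
#' d <- generate_dataset(2, seed = 1)
#' head(extract_features(d))
#' @export
extract_features <- function(table) {
  need <- c("breath_id", "R", "C", "time_step", "u_in")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  dt <- data.table::as.data.table(table)
  grp_first_zero_diff <- function(v) c(0, diff(v))
  dt[, `:=`(
    delta = R * C,
    cisv = cumsum(u_in),
    integral = grp_first_zero_diff(time_step),
    differential = grp_first_zero_diff(u_in)
  ), by = "breath_id"]
  as.data.frame(dt)
}

#' Keep the discriminative engineered features
#'
#' Drops the `differential` column, which fails to separate the pressure
#' distributions across lung settings, while `delta`, `cisv` and
#' `integral` are preserved.  Idempotent.
#'
#' @param table A feature table (see [extract_features()]).
#' @param keep_all If `TRUE`, return the table unchanged.
#' @return The table without `differential` (unless `keep_all`).
#' @export
select_features <- function(table, keep_all = FALSE) {
  if (keep_all) return(table)
  table[setdiff(names(table), "differential")]
}
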