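#' Lung and circuit configuration for the breath simulator
#'
#' Single-compartment linear lung mechanics: airway resistance `R`
#' (cmH2O/L/s) restricts flow, compliance `C` (mL/cmH2O) sets the volume
#' change per unit pressure, and a PEEP baseline keeps the circuit above
#' atmospheric pressure at end-exhalation.  A small fraction of the
#' inspiratory flow can escape through an imperfect expiratory valve
#' (`leak_frac`), and observation noise is additive Gaussian on the
#' recorded pressure only.
#'
#' @param R Airway resistance, cmH2O/L/s; the emulated bench uses
#'   5, 20 or 50.
#' @param C Compliance, mL/cmH2O; 10, 20 or 50 on the bench.
#' @param peep Positive end-expiratory pressure, cmH2O (default 5).
#' @param leak_frac Fraction of inspiratory flow lost to leak while the
#'   expiratory valve is closed (default 0.01).
#' @param noise_sd Standard deviation of the pressure observation noise,
#'   cmH2O (default 0.05).
#' @param q_max Source flow at full inspiratory-valve opening, L/s
#'   (default 1).
#' @return A list of class `lung_config`.
#' @export
lung_config <- function(R = 20, C = 20, peep = 5, leak_frac = 0.01,
                        noise_sd = 0.05, q_max = 1) {
  if (R <= 0 || C <= 0) stop("R and C must be positive")
  if (peep < 0) stop("peep must be non-negative")
  if (leak_frac < 0 || leak_frac >= 1) stop("leak_frac must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (q_max <= 0) stop("q_max must be positive")
  structure(list(R = R, C = C, peep = peep, leak_frac = leak_frac,
                 noise_sd = noise_sd, q_max = q_max),
            class = "lung_config")
}

#' Randomized two-phase valve profile
#'
#' One breath: an inhalation phase (expiratory valve closed, `u_out = 0`)
#' of about one second during which the inspiratory valve follows a
#' randomized ramp to a plateau in `[0, 100]`, then an exhalation phase
#' (`u_out = 1`, `u_in = 0`) for the remainder.  The phase boundary is
#' jittered by +/-10 %.  Uses R's current random stream.
#'
#' @param n_steps Number of samples per breath (default 80).
#' @param total_time Breath duration in seconds (default 3).
#' @param insp_time Nominal inhalation duration in seconds (default 1).
#' @return A list with `time_step` (starting at 0, uniform spacing),
#'   `u_in` in `[0, 100]` and binary `u_out`.
#' @export
valve_profile <- function(n_steps = 80L, total_time = 3.0, insp_time = 1.0) {
  stopifnot(n_steps >= 2, total_time > 0, insp_time > 0,
            insp_time < total_time)
  dt <- total_time / n_steps
  time_step <- (seq_len(n_steps) - 1L) * dt
  t_insp <- insp_time * stats::runif(1, 0.9, 1.1)
  plateau <- stats::runif(1, 20, 100)
  ramp_frac <- stats::runif(1, 0.1, 0.6)  # fraction of inhalation spent ramping
  t_ramp <- ramp_frac * t_insp
  u_in <- ifelse(time_step < t_insp,
                 pmin(plateau, plateau * time_step / t_ramp),
                 0)
  u_out <- as.integer(time_step >= t_insp)
  list(time_step = time_step, u_in = pmin(pmax(u_in, 0), 100), u_out = u_out)
}

#' Simulate one breath
#'
#' Integrates the single-compartment model on the sampling grid: net flow
#' into the lung is `q_in * (1 - leak_frac) - q_out` with
#' `q_in = q_max * u_in / 100`; the observed pressure combines the PEEP
#' baseline, the elastic recoil `V / C` and the resistive drop
#' `R * dV/dt`, plus optional Gaussian observation noise, and passive
#' exhalation is `q_out = u_out * (P - PEEP) / R`.  The outflow is
#' coupled to the pressure it creates, so each step solves the pair
#' self-consistently (a closed form exists; see the methods vignette),
#' which keeps the exhalation decay smooth, non-negative in flow, and
#' the pressure at or above PEEP while the expiratory valve is open.
#' Volume is in litres and compliance in mL/cmH2O, so the elastic term
#' is `1000 * V / C` cmH2O.
#'
#' @param lung A [lung_config()].
#' @param profile A valve profile (see [valve_profile()]).
#' @param breath_id Integer identifier stored with the breath.
#' @return A data.frame with columns `breath_id`, `R`, `C`, `time_step`,
#'   `u_in`, `u_out`, `pressure`, plus the latent `volume` (litres) as an
#'   attribute `"volume"` for diagnostic checks.
#' @export
simulate_breath <- function(lung, profile, breath_id = 1L) {
  stopifnot(inherits(lung, "lung_config"))
  n <- length(profile$time_step)
  if (n < 2L) stop("profile must contain at least two samples")
  dt <- diff(profile$time_step)
  if (any(dt <= 0)) stop("time steps must be strictly increasing")
  dt <- c(dt[1], dt)  # step width used for sample k's integration

  V <- numeric(n)      # lung volume, litres
  P <- numeric(n)
  v <- 0
  for (k in seq_len(n)) {
    q_in <- lung$q_max * profile$u_in[k] / 100 * (1 - lung$leak_frac)
    if (profile$u_out[k] > 0) {
      # solve q_out = (P - PEEP)/R jointly with the pressure equation:
      # with a = 1000*dt/C + R and b = 1000*v/C,
      # q_out = (b + a*q_in) / (R + a)  (>= 0 whenever v, q_in >= 0)
      a <- 1000 * dt[k] / lung$C + lung$R
      b <- 1000 * v / lung$C
      q_out <- (b + a * q_in) / (lung$R + a)
    } else {
      q_out <- 0
    }
    dvdt <- q_in - q_out
    v <- v + dvdt * dt[k]
    p_clean <- lung$peep + 1000 * v / lung$C + lung$R * dvdt
    P[k] <- p_clean + if (lung$noise_sd > 0) stats::rnorm(1, 0, lung$noise_sd) else 0
    V[k] <- v
  }
  out <- data.frame(breath_id = as.integer(breath_id),
                    R = lung$R, C = lung$C,
                    time_step = profile$time_step,
                    u_in = profile$u_in, u_out = profile$u_out,
                    pressure = P)
  attr(out, "volume") <- V
  out
}

#' Generate a synthetic ventilator dataset
#'
#' Draws breaths over a grid of (R, C) lung settings and emits a table in
#' the public ventilator-pressure schema: columns `id`, `breath_id`, `R`,
#' `C`, `time_step`, `u_in`, `u_out`, `pressure`.  With
#' `stratified = TRUE` the grid pairs are cycled so `n_breaths = 9` on the
#' full 3x3 grid covers each pair exactly once.
#'
#' @param n_breaths Number of breaths to simulate.
#' @param grid Data.frame with columns `R` and `C`; defaults to the full
#'   3x3 grid R in \{5, 20, 50\} x C in \{10, 20, 50\}.
#' @param seed Integer seed; the whole table is reproducible from it.
#' @param stratified Cycle deterministically through the grid (default)
#'   instead of sampling pairs uniformly.
#' @param peep,leak_frac,noise_sd,q_max Circuit constants passed to
#'   [lung_config()].
#' @param n_steps,total_time Sampling grid passed to [valve_profile()].
#' @return A data.frame in the schema above, `n_breaths * n_steps` rows.
#' @examples
#' d <- generate_dataset(9, seed = 1)
#' nrow(d)  # 720
#' @export
generate_dataset <- function(n_breaths, grid = default_rc_grid(), seed = 1L,
                             stratified = TRUE, peep = 5, leak_frac = 0.01,
                             noise_sd = 0.05, q_max = 1,
                             n_steps = 80L, total_time = 3.0) {
  if (n_breaths < 1L) stop("n_breaths must be at least 1")
  if (is.null(grid) || nrow(grid) < 1L) stop("grid must contain at least one (R, C) pair")
  set.seed(seed)
  rows <- if (stratified) {
    rep_len(seq_len(nrow(grid)), n_breaths)
  } else {
    sample.int(nrow(grid), n_breaths, replace = TRUE)
  }
  breaths <- vector("list", n_breaths)
  for (b in seq_len(n_breaths)) {
    lung <- lung_config(R = grid$R[rows[b]], C = grid$C[rows[b]],
                        peep = peep, leak_frac = leak_frac,
                        noise_sd = noise_sd, q_max = q_max)
    prof <- valve_profile(n_steps = n_steps, total_time = total_time)
    breaths[[b]] <- simulate_breath(lung, prof, breath_id = b)
  }
  out <- do.call(rbind, breaths)
  rownames(out) <- NULL
  cbind(id = seq_len(nrow(out)), out)
}

#' The full 3x3 resistance-compliance grid
#'
#' @return A data.frame of the nine (R, C) combinations with R in
#'   \{5, 20, 50\} cmH2O/L/s and C in \{10, 20, 50\} mL/cmH2O.
#' @export
default_rc_grid <- function() {
  expand.grid(R = c(5, 20, 50), C = c(10, 20, 50))
}
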