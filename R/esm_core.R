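#' ESM parameter set
#'
#' Subject-level constants of the epidemic spreading model. `beta0` and
#' `delta0` are the global production and clearance amplitudes (clamped to
#' \[0,1\] when used as rates); `noise_mean`/`noise_sd` parameterize the
#' additive Gaussian noise (probability/day and probability/day^(1/2));
#' `velocity` is the misfolded-protein transport speed along fibers (mm/day),
#' which sets the transmission delay of every connection; `sigmoid_slope` and
#' `sigmoid_mid` shape the production sigmoid; `clearance_decay` is the rate
#' at which clearance capacity collapses with local deposition.
#'
#' Default shape constants make the local dynamics bistable and the global
#' dynamics transport-limited. Production turns on once deposition is
#' established (`sigmoid_mid = 0.3`, `sigmoid_slope = 10`): trace levels
#' produce almost nothing, so a region stays quiescent until infectious
#' input actually arrives. Clearance capacity collapses steeply with plaque
#' load (`clearance_decay = 3.5`, ~30-fold at full deposition), so deposits
#' persist once established - the clearance-deficiency mechanism at the
#' model's core. Seeds start as an established focus
#' (`p_seed_init = 0.6`), above the basin boundary of the bistable local
#' dynamics across the physiological amplitude ranges. The default
#' transport speed of 0.01 mm/day turns anatomical fiber lengths of 20-150
#' mm into inter-region lags of roughly 5-40 years, so whole-brain
#' progression unfolds over decades within the default 50-year horizon.
#'
#' @param beta0 production constant, > 0.
#' @param delta0 clearance constant, > 0.
#' @param noise_mean Gaussian noise mean (mu), probability/day.
#' @param noise_sd Gaussian noise standard deviation (sigma), >= 0.
#' @param velocity transport speed V_MP in mm/day, > 0.
#' @param dt integration step in days.
#' @param horizon_days simulated horizon in days (default 18250 = 50 years).
#' @param p_seed_init initial deposition probability on seed regions, (0, 1].
#' @param sigmoid_slope production sigmoid slope, > 0.
#' @param sigmoid_mid production sigmoid midpoint, in (0, 1).
#' @param clearance_decay exponential decay rate of clearance with
#'   deposition, > 0.
#' @return an object of class `esm_params`.
#' @export
esm_params <- function(beta0, delta0, noise_mean = 0.001, noise_sd = 0,
                       velocity = 0.01, dt = 1, horizon_days = 18250L,
                       p_seed_init = 0.6, sigmoid_slope = 10,
                       sigmoid_mid = 0.45, clearance_decay = 4.5) {
  stopifnot(beta0 >= 0, delta0 >= 0, noise_sd >= 0, velocity > 0, dt > 0,
            horizon_days >= 1, p_seed_init > 0, p_seed_init <= 1,
            sigmoid_slope > 0, sigmoid_mid > 0, sigmoid_mid < 1,
            clearance_decay > 0)
  structure(list(beta0 = beta0, delta0 = delta0, noise_mean = noise_mean,
                 noise_sd = noise_sd, velocity = velocity, dt = dt,
                 horizon_days = as.integer(round(horizon_days / dt)),
                 horizon = horizon_days,
                 p_seed_init = p_seed_init, sigmoid_slope = sigmoid_slope,
                 sigmoid_mid = sigmoid_mid, clearance_decay = clearance_decay),
            class = "esm_params")
}

#' @export
print.esm_params <- function(x, ...) {
  cat(sprintf(paste0("esm_params: beta0=%.3g delta0=%.3g sigma=%.3g ",
                     "V=%.3g mm/day horizon=%d days dt=%.3g\n"),
              x$beta0, x$delta0, x$noise_sd, x$velocity, x$horizon, x$dt))
  invisible(x)
}

#' Gini coefficient of a deposition vector
#'
#' Statistical dispersion G = sum_ij |x_i - x_j| / (2 n^2 mean(x)), the
#' global inequality measure that splits regional production into extrinsic
#' (exported) and intrinsic (retained) parts. Returns 0 for an all-zero
#' vector (degenerate perfectly equal state).
#'
#' @param x non-empty vector of non-negative values.
#' @return G in \[0, 1).
#' @export
gini_coefficient <- function(x) {
  if (length(x) == 0) stop("x must be non-empty")
  if (any(x < 0)) stop("negative entries not allowed")
  s <- sum(x)
  if (s <= 0) return(0)
  n <- length(x)
  xs <- sort(x)
  g <- (2 * sum(seq_len(n) * xs) - (n + 1) * s) / (n * s)
  max(g, 0)
}

#' Production ("infection") rate as a function of local deposition
#'
#' Normalized logistic scaled by the production amplitude:
#' `beta_total = min(beta0, 1) * L(p)`, where L is the logistic
#' `1/(1 + exp(-slope (p - mid)))` rescaled so L(0) = 0 and L(1) = 1.
#' High local deposition implies a high probability of producing new
#' infectious-like factors (seeding/nucleation).
#'
#' @param p_dep deposition probability (vectorized).
#' @param beta0 production amplitude.
#' @param slope,mid sigmoid shape constants.
#' @return production rates in \[0, min(beta0, 1)\].
#' @export
infection_rate <- function(p_dep, beta0, slope = 10, mid = 0.45) {
  stopifnot(all(p_dep >= 0 & p_dep <= 1), beta0 >= 0, slope > 0,
            mid > 0, mid < 1)
  s <- function(p) 1 / (1 + exp(-slope * (p - mid)))
  min(beta0, 1) * (s(p_dep) - s(0)) / (s(1) - s(0))
}

#' Clearance rate as a function of local deposition
#'
#' `delta = min(delta0, 1) * exp(-decay * p)`: deposition brings
#' inflammation and cell death, so the capacity to remove infectious-like
#' agents decays exponentially with local burden.
#'
#' @param p_dep deposition probability (vectorized).
#' @param delta0 clearance amplitude.
#' @param decay exponential decay constant.
#' @return clearance rates in (0, min(delta0, 1)\].
#' @export
clearance_rate <- function(p_dep, delta0, decay = 4.5) {
  stopifnot(all(p_dep >= 0 & p_dep <= 1), delta0 >= 0, decay > 0)
  min(delta0, 1) * exp(-decay * p_dep)
}

#' Split total production into extrinsic and intrinsic parts
#'
#' The global deposition inequality (Gini) g routes production outward:
#' `beta_ext = g * beta_total` diffuses toward connected regions,
#' `beta_int = (1 - g) * beta_total` stays in place. The parts always sum
#' back to the total.
#'
#' @param beta_total vector of total production rates in \[0, 1\].
#' @param gini inequality coefficient in \[0, 1).
#' @return list with `beta_ext` and `beta_int`.
#' @export
split_rates <- function(beta_total, gini) {
  stopifnot(gini >= 0, gini < 1, all(beta_total >= 0 & beta_total <= 1))
  list(beta_ext = gini * beta_total, beta_int = (1 - gini) * beta_total)
}

#' Probability of receiving infectious-like factors
#'
#' Probabilistic accumulation of exogenous and endogenous factors:
#' `1 - (1 - beta_int_i) * prod_j (1 - acp_ji * beta_ext_j)`, where each
#' sender's extrinsic rate is evaluated at its delayed deposition state.
#'
#' @param acp_col_i connection probabilities from every sender to region i.
#' @param beta_ext_delayed extrinsic rates of the senders at their delayed
#'   states.
#' @param beta_int_i intrinsic rate of region i.
#' @param self optional index of region i within `acp_col_i`, excluded from
#'   the product (self-transmission enters through `beta_int_i`).
#' @return reception probability in \[0, 1\].
#' @export
reception_probability <- function(acp_col_i, beta_ext_delayed, beta_int_i,
                                  self = NULL) {
  stopifnot(all(acp_col_i >= 0 & acp_col_i <= 1),
            all(beta_ext_delayed >= 0 & beta_ext_delayed <= 1),
            beta_int_i >= 0, beta_int_i <= 1)
  terms <- acp_col_i * beta_ext_delayed
  if (!is.null(self)) terms <- terms[-self]
  1 - (1 - beta_int_i) * prod(1 - terms)
}

#' Transmission delay matrix in integration steps
#'
#' `tau_ji = round(fiber_length_ji / velocity / dt)` steps.
#' @param conn a `connectome`.
#' @param params an `esm_params`.
#' @return integer N x N matrix of delays in steps.
#' @export
transmission_delays <- function(conn, params) {
  d <- round(conn$fiber_length / params$velocity / params$dt)
  storage.mode(d) <- "integer"
  d
}

#' Simulate the epidemic spreading model
#'
#' Euler-Maruyama integration of the delayed stochastic model on a daily (or
#' `dt`-day) grid:
#' `P_i(t+dt) = clip( P_i + dt * ((1 - P_i) R_i - P_i delta_i) + mu dt +
#' sigma sqrt(dt) Z )`, where the reception probability `R_i` accumulates the
#' intrinsic production of i and the delayed extrinsic production of every
#' connected sender (delay = fiber length / velocity), and all rates are
#' recomputed each step from the current state with the current Gini split.
#' States are clipped to \[0, 1\] after every step.
#'
#' @param conn a `connectome`.
#' @param params an `esm_params`.
#' @param seeds non-empty integer vector of outbreak region indices; they
#'   start at `params$p_seed_init`, all other regions at 0.
#' @param rng_seed integer seed for the noise draws, or `NULL` for a
#'   deterministic trajectory (noise term omitted; `noise_mean` still acts
#'   as a deterministic drift).
#' @return an `esm_trajectory`: list with `time_days` (0..horizon), `p`
#'   (T x N matrix of deposition probabilities), `seeds`, `params`,
#'   `rng_seed`.
#' @export
simulate_esm <- function(conn, params, seeds, rng_seed = NULL) {
  stopifnot(inherits(conn, "connectome"), inherits(params, "esm_params"))
  n <- n_regions(conn)
  seeds <- as.integer(seeds)
  if (length(seeds) == 0) stop("seeds must be non-empty")
  if (any(seeds < 1 | seeds > n)) stop("seed index out of range")
  n_steps <- params$horizon_days
  p0 <- numeric(n)
  p0[seeds] <- params$p_seed_init
  delay <- transmission_delays(conn, params)
  noise <- NULL
  if (!is.null(rng_seed) && params$noise_sd > 0) {
    noise <- with_rng_seed(rng_seed,
                           matrix(rnorm(n_steps * n), n_steps, n))
  }
  p <- esm_simulate_cpp(conn$acp, delay, p0, n_steps, params$dt,
                        params$beta0, params$delta0, params$noise_mean,
                        params$noise_sd, params$sigmoid_slope,
                        params$sigmoid_mid, params$clearance_decay, noise)
  colnames(p) <- conn$labels
  structure(list(time_days = seq(0, by = params$dt, length.out = n_steps + 1),
                 p = p, seeds = seeds, params = params, rng_seed = rng_seed),
            class = "esm_trajectory")
}

#' @export
print.esm_trajectory <- function(x, ...) {
  cat(sprintf("esm_trajectory: %d regions, %d days, seeds {%s}, final mean P %.3f\n",
              ncol(x$p), max(x$time_days),
              paste(x$seeds, collapse = ","),
              mean(x$p[nrow(x$p), ])))
  invisible(x)
}

#' Write a trajectory to TSV with a JSON metadata sidecar
#'
#' @param traj an `esm_trajectory`.
#' @param path TSV destination (day x region table with a `day` column).
#' @param meta_path optional JSON sidecar (parameters, seeds, rng seed).
#' @return invisibly, `traj`.
#' @export
write_trajectory <- function(traj, path, meta_path = NULL) {
  df <- data.frame(day = traj$time_days, traj$p, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path)) {
    meta <- list(params = unclass(traj$params), seeds = traj$seeds,
                 rng_seed = traj$rng_seed)
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(traj)
}

#' Marginalized global production and clearance rates
#'
#' Averages the production and clearance rate functions over all possible
#' deposition levels: `beta_eff = integral_0^1 infection_rate(p) dp`,
#' `delta_eff = integral_0^1 clearance_rate(p) dp`, by composite trapezoidal
#' quadrature on a fixed 1001-point grid. These are the per-subject global
#' summary rates.
#'
#' @param params an `esm_params`.
#' @return list with `beta_eff` and `delta_eff`.
#' @export
marginal_rates <- function(params) {
  p <- seq(0, 1, length.out = 1001)
  h <- p[2] - p[1]
  trap <- function(y) h * (sum(y) - (y[1] + y[length(y)]) / 2)
  b <- if (params$beta0 > 0) {
    infection_rate(p, params$beta0, params$sigmoid_slope, params$sigmoid_mid)
  } else rep(0, length(p))
  d <- clearance_rate(p, params$delta0, params$clearance_decay)
  list(beta_eff = trap(b), delta_eff = trap(d))
}
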