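#' Environmental-noise Metropolis-Hastings chain
#'
#' Environmental noise is a population-wide perturbation `delta` of a log
#' input value that persists across generations. Each generation one
#' Metropolis-Hastings update is made: a proposal `delta + N(0, sigma_step^2)`
#' is accepted with probability
#' `min(1, exp((delta^2 - delta_prop^2) / (2 sigma_env^2)))`, otherwise the
#' perturbation is unchanged. The stationary law of the chain is
#' `N(0, sigma_env^2)`; the proposal-to-stationary ratio
#' `sigma_step / sigma_env` (default 0.25) sets the autocorrelation time
#' (about 27 generations at 0.25, as measured by [autocorr_time()]).
#'
#' @param n_steps Number of generations to simulate.
#' @param sigma_env Stationary standard deviation of the perturbation.
#' @param sigma_step Proposal standard deviation (default
#'   `0.25 * sigma_env`). Zero freezes the chain.
#' @param delta0 Initial perturbation.
#' @return A tibble with columns `step` and `delta`.
#' @examples
#' ch <- env_noise_chain(5e4, sigma_env = 0.1)
#' autocorr_time(ch$delta)
#' @export
env_noise_chain <- function(n_steps, sigma_env, sigma_step = 0.25 * sigma_env,
                            delta0 = 0) {
  stopifnot(n_steps >= 1, sigma_env >= 0, sigma_step >= 0)
  delta <- cpp_env_chain(as.integer(n_steps), sigma_env, sigma_step, delta0)
  tibble(step = seq_len(n_steps), delta = delta)
}

#' Developmental noise and environmental shifts on input values
#'
#' `apply_dev_noise()` perturbs every input value of every individual
#' independently on the log scale: `ln x_e = ln x + N(0, sigma_dev^2)`.
#' Outputs are therefore always positive, and `sigma_dev = 0` is the
#' identity. `apply_env_shift()` adds a fixed quantity `delta_env` to the log
#' of every input (the same shift for all individuals), the deterministic
#' intervention used to model an abrupt environmental change.
#'
#' @param inputs Positive numeric vector, matrix, or data frame of input
#'   values.
#' @param sigma_dev Standard deviation of the log-scale perturbation.
#' @param delta_env Log-scale shift; a scalar, or one value per input column.
#' @return Object of the same shape as `inputs`.
#' @export
apply_dev_noise <- function(inputs, sigma_dev) {
  stopifnot(sigma_dev >= 0)
  reshape_like(inputs, function(x) {
    if (any(x <= 0)) abort("input values must be strictly positive")
    if (sigma_dev == 0) return(x)
    exp(log(x) + rnorm(length(x), 0, sigma_dev))
  })
}

#' @rdname apply_dev_noise
#' @export
apply_env_shift <- function(inputs, delta_env) {
  if (is.data.frame(inputs) || is.matrix(inputs)) {
    m <- if (is.data.frame(inputs)) as.matrix(inputs) else inputs
    if (any(m <= 0)) abort("input values must be strictly positive")
    if (length(delta_env) == 1) delta_env <- rep(delta_env, ncol(m))
    stopifnot(length(delta_env) == ncol(m))
    out <- exp(sweep(log(m), 2, delta_env, "+"))
    if (is.data.frame(inputs)) {
      res <- as_tibble(as.data.frame(out))
      names(res) <- names(inputs)
      res
    } else {
      out
    }
  } else {
    if (any(inputs <= 0)) abort("input values must be strictly positive")
    exp(log(inputs) + delta_env)
  }
}

reshape_like <- function(inputs, f) {
  if (is.data.frame(inputs)) {
    out <- f(as.matrix(inputs))
    res <- as_tibble(as.data.frame(out))
    names(res) <- names(inputs)
    res
  } else {
    f(inputs)
  }
}

#' Autocorrelation time of a stationary series
#'
#' Summarizes the decay of the empirical autocorrelation function (ACF) of a
#' series as a single time, in the units of the series index (generations).
#' Three estimators are provided:
#'
#' * `"half_life"` (default): the lag at which the ACF first falls below
#'   1/2, linearly interpolated between adjacent lags. This is the
#'   convention under which the default environmental-noise chain
#'   (`sigma_step/sigma_env = 0.25`) has an autocorrelation time of about
#'   27 generations.
#' * `"exponential"`: the decay time `T` of a fit `ACF(tau) = exp(-tau/T)`
#'   over lags up to the first zero crossing (about `ln 2` times longer than
#'   the half-life for an exponentially decaying ACF).
#' * `"integrated"`: `1/2 + sum of the ACF` up to the first zero crossing.
#'
#' @param x Numeric series (e.g. the `delta` column of
#'   [env_noise_chain()]). Should be much longer than the expected
#'   correlation time.
#' @param method Estimator, see above.
#' @param lag_max Maximum lag examined (default `10 * sqrt(length(x))`,
#'   capped at `length(x) - 1`).
#' @return The autocorrelation time (scalar). Errors if the ACF has not
#'   decayed within `lag_max` (series too short or non-stationary).
#' @export
autocorr_time <- function(x, method = c("half_life", "exponential",
                                        "integrated"),
                          lag_max = NULL) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 100) abort("series too short to estimate an autocorrelation time")
  if (is.null(lag_max)) lag_max <- min(n - 1, ceiling(10 * sqrt(n)))
  rho <- drop(acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf)[-1]
  zero <- which(rho <= 0)[1]
  if (is.na(zero) && rho[lag_max] > 0.5) {
    abort("autocorrelation has not decayed within lag_max; series too short or non-stationary")
  }
  upto <- if (is.na(zero)) lag_max else zero - 1L
  if (method == "half_life") {
    vals <- c(1, rho)
    below <- which(vals < 0.5)[1]
    if (is.na(below)) {
      abort("autocorrelation never fell below 1/2 within lag_max")
    }
    hi <- vals[below - 1]
    lo <- vals[below]
    (below - 2) + (hi - 0.5) / (hi - lo)
  } else if (method == "exponential") {
    lags <- seq_len(upto)
    keep <- rho[lags] > 0
    lags <- lags[keep]
    if (length(lags) < 2) return(0.5) # ACF drops immediately: white-noise-like
    -1 / unname(coef(lm(log(rho[lags]) ~ 0 + lags)))
  } else {
    0.5 + sum(rho[seq_len(upto)])
  }
}
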