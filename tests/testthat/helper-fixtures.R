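# Small simulations shared across tests; kept tiny so the default run stays fast.

small_sim <- function(k = 0, N = 200, generations = 4000, burn_in = 1000,
                      sample_every = 1000, sigma_dev = 0.05,
                      sigma_env = 0.05, mu = 1e-4, sigma_mu = 1, s = 1,
                      seed = 1, landscape = landscape_lp(k), ...) {
  cfg <- sim_config(N = N, mu = mu, sigma_mu = sigma_mu,
                    generations = generations, burn_in = burn_in,
                    sample_every = sample_every, sigma_dev = sigma_dev,
                    sigma_env = sigma_env, s = s, ...)
  run_simulation(landscape, cfg, seed = seed)
}

# a deterministic single-time-point snapshot tibble for case-control tests
toy_snapshot <- function(z, xe = NULL, w = NULL, generation = 1) {
  n <- length(z)
  if (is.null(xe)) xe <- cbind(z, z)
  tibble::tibble(
    generation = generation, id = seq_len(n),
    x_1 = xe[, 1], x_2 = xe[, 2],
    xh_1 = xe[, 1], xh_2 = xe[, 2],
    xe_1 = xe[, 1], xe_2 = xe[, 2],
    z = z, z_h = z,
    w = if (is.null(w)) ridgesim::fitness(z) else w,
    rarest_freq = 1
  )
}
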