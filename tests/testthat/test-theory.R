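grid_axis <- seq(-0.6, 2.4, length.out = 61)

test_that("effective fitness reduces to raw fitness at zero noise and keeps symmetry", {
  eff0 <- effective_fitness(landscape_lp(0.1), 0, grid_axis, grid_axis)
  expect_identical(eff0$w_e, eff0$w)
  eff <- effective_fitness(landscape_lp(0), 0.2, grid_axis, grid_axis,
                           nodes = 21)
  expect_true(all(eff$w_e > 0 & eff$w_e <= 1))
  # x <-> y symmetry of the averaged landscape
  m <- matrix(eff$w_e, length(grid_axis))
  expect_lt(max(abs(m - t(m))), 1e-9)
})

test_that("quadrature is converged at 21 nodes (doubling changes little)", {
  # the k = 0 integrand is kinked at the ridge, so convergence is slow but
  # must keep improving under node doubling
  ax <- seq(-0.2, 1.2, length.out = 15)
  a <- effective_fitness(landscape_lp(0), 0.2, ax, ax, nodes = 21)
  b <- effective_fitness(landscape_lp(0), 0.2, ax, ax, nodes = 43)
  c <- effective_fitness(landscape_lp(0), 0.2, ax, ax, nodes = 87)
  d1 <- max(abs(a$w_e - b$w_e))
  d2 <- max(abs(b$w_e - c$w_e))
  expect_lt(d1, 2e-3)
  expect_lt(d2, d1)
  # smooth landscape: fast convergence
  sa <- effective_fitness(landscape_poly(2, 0.5), 0.2, ax, ax, nodes = 21)
  sb <- effective_fitness(landscape_poly(2, 0.5), 0.2, ax, ax, nodes = 43)
  expect_lt(max(abs(sa$w_e - sb$w_e)), 1e-6)
})

test_that("noise creates an effective-fitness peak near the sharp corner", {
  # the peak sits within a noise-width of the corner (shifted slightly up
  # the diagonal); the arms plateau strictly below it
  eff <- effective_fitness(landscape_lp(0), 0.2, grid_axis, grid_axis)
  near <- abs(eff$ln_x) <= 0.5 & abs(eff$ln_y) <= 0.5
  arm <- eff$w_e[which.min(abs(eff$ln_x - 2) + abs(eff$ln_y))]
  expect_gt(max(eff$w_e[near]), arm + 0.005)
  expect_equal(max(eff$w_e), max(eff$w_e[near]))
})

test_that("arm profiles are corner-normalized, flat at low noise, biased at high", {
  low <- arm_profile(effective_fitness(landscape_lp(1e-4), 0.05, grid_axis,
                                       grid_axis))
  expect_equal(low$profile[which.min(abs(low$x_prime))], 1)
  right <- low[low$x_prime >= 0.3, ]
  expect_lt(max(abs(right$profile - 1)), 0.005)
  high <- arm_profile(effective_fitness(landscape_lp(1e-4), 0.2, grid_axis,
                                        grid_axis))
  far <- high[high$x_prime > 0.5, ]
  # decreasing away from the corner region, settling below the peak
  expect_true(all(diff(far$profile) < 1e-8))
  near_max <- max(high$profile[high$x_prime >= 0 & high$x_prime <= 0.6])
  expect_gt(near_max, min(far$profile) + 0.005)
})

test_that("a flat profile gives a neutral chain with linearly falling exceedance", {
  prof <- tibble::tibble(x_prime = seq(0, 3, by = 0.1),
                         w_e = rep(0.9, 31))
  chain <- build_chain(prof, N = 100, sigma_mu = 3)
  pi_st <- stationary_distribution(chain)
  # wide uniform proposals on a flat profile: near-uniform stationary law
  # (small edge bias from the discretized, row-normalized proposal)
  expect_equal(pi_st$prob, rep(1 / 31, 31), tolerance = 0.1)
  d <- seq(0, 3, by = 0.5)
  exc <- exceedance(pi_st, d)
  expect_equal(exc[1], 1)
  fit <- lm(exc ~ d)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_lt(coef(fit)[2], 0)
})

test_that("the stationary law matches a long Monte-Carlo run of the chain", {
  ax <- seq(-0.2, 2.2, length.out = 41)
  prof <- arm_profile(effective_fitness(landscape_lp(1e-4), 0.2, ax, ax))
  prof <- prof[prof$x_prime >= 0, ]
  chain <- build_chain(prof, N = 20, sigma_mu = 0.5)
  pi_st <- stationary_distribution(chain)
  expect_equal(sum(pi_st$prob), 1)
  set.seed(40)
  n_steps <- 2e6
  visits <- simulate_chain(chain, n_steps)
  occ <- tabulate(visits[-(1:1e4)], nrow(pi_st)) / (n_steps - 1e4)
  tv <- 0.5 * sum(abs(occ - pi_st$prob))
  expect_lt(tv, 0.02)
})

test_that("chain localization strengthens monotonically with noise level", {
  ax <- seq(-0.6, 3, length.out = 73)
  exc_at_1 <- vapply(c(0.1, 0.2, 0.3), function(noise) {
    prof <- arm_profile(effective_fitness(landscape_lp(1e-4), noise, ax, ax))
    prof <- prof[prof$x_prime >= 0, ]
    ch <- build_chain(prof, N = 300, sigma_mu = 1)
    exceedance(stationary_distribution(ch), 1)
  }, 0)
  expect_true(all(diff(exc_at_1) < 0))
})

test_that("both fixation forms have the neutral limit 1/(2N)", {
  prof <- tibble::tibble(x_prime = 0:5, w_e = rep(0.8, 6))
  for (fx in c("kimura", "metropolis")) {
    ch <- build_chain(prof, N = 50, sigma_mu = 1, fixation = fx)
    # off-diagonal transition mass equals proposal mass times 1/(2N)
    off <- ch$T
    diag(off) <- 0
    expect_equal(rowSums(off), rep(1 / 100, 6), tolerance = 1e-10)
  }
})
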