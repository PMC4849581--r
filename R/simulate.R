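#' Simulation configuration
#'
#' Validated bundle of population-genetic, noise and selection parameters
#' for [run_simulation()]. Defaults are the full-scale study conditions: a
#' population of 5000 diploids evolved for 10 million generations with the
#' first 1 million discarded, mutation rate 1e-4 per allele per generation,
#' free recombination, allele values capped at 100, and sampling every
#' 10,000 generations. Desk-scale work usually overrides `N`, `generations`,
#' `burn_in` and `sample_every`.
#'
#' @param N Population size (diploid individuals).
#' @param mu Mutation rate per allele per generation, in `[0, 1]`.
#' @param sigma_mu Log-scale sd of the mutational step.
#' @param recomb Probability of switching chromosomes between adjacent loci,
#'   in `[0, 0.5]` (0.5 = free recombination).
#' @param allele_cap Maximum allele value.
#' @param generations Total generations to run.
#' @param burn_in Generations discarded before sampling starts.
#' @param sample_every Sampling cadence (generations).
#' @param sigma_dev Developmental noise level (log-scale sd, per individual
#'   and input).
#' @param sigma_env Environmental noise stationary sd (population-wide,
#'   autocorrelated).
#' @param sigma_step_ratio Proposal-to-stationary sd ratio of the
#'   environmental chain (default 0.25, giving an autocorrelation time of
#'   about 27 generations).
#' @param s Selection factor of the stabilizing fitness function.
#' @param z_opt Optimal phenotype value.
#' @param start_inputs Optional explicit starting input values (required for
#'   landscapes without a diagonal corner).
#' @return A `sim_config` object (validated named list).
#' @export
sim_config <- function(N = 5000, mu = 1e-4, sigma_mu = 1, recomb = 0.5,
                       allele_cap = 100, generations = 1e7, burn_in = 1e6,
                       sample_every = 1e4, sigma_dev = 0, sigma_env = 0,
                       sigma_step_ratio = 0.25, s = 1, z_opt = 1,
                       start_inputs = NULL) {
  cfg <- list(N = as.integer(N), mu = mu, sigma_mu = sigma_mu,
              recomb = recomb, allele_cap = allele_cap,
              generations = generations, burn_in = burn_in,
              sample_every = sample_every, sigma_dev = sigma_dev,
              sigma_env = sigma_env, sigma_step_ratio = sigma_step_ratio,
              s = s, z_opt = z_opt, start_inputs = start_inputs)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check <- function(ok, msg) if (!ok) abort(paste0("invalid configuration: ", msg))
  check(cfg$N >= 2, "N must be at least 2")
  check(cfg$mu >= 0 && cfg$mu <= 1, "mu must lie in [0, 1]")
  check(cfg$sigma_mu >= 0, "sigma_mu must be non-negative")
  check(cfg$recomb >= 0 && cfg$recomb <= 0.5, "recomb must lie in [0, 0.5]")
  check(cfg$allele_cap > 0, "allele_cap must be positive")
  check(cfg$generations >= 1, "generations must be positive")
  check(cfg$burn_in >= 0 && cfg$burn_in < cfg$generations,
        "burn_in must be non-negative and below generations")
  check(cfg$sample_every >= 1, "sample_every must be positive")
  check(cfg$sigma_dev >= 0, "sigma_dev must be non-negative")
  check(cfg$sigma_env >= 0, "sigma_env must be non-negative")
  check(cfg$sigma_step_ratio >= 0, "sigma_step_ratio must be non-negative")
  check(cfg$s >= 0, "s must be non-negative")
  check(cfg$z_opt > 0, "z_opt must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  flat <- x[!vapply(x, is.null, TRUE)]
  cat(paste0("  ", names(flat), " = ", unlist(lapply(flat, format)),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Run a forward-time evolutionary simulation
#'
#' Evolves a diploid Wright-Fisher population on a landscape under
#' stabilizing selection, with environmental and developmental phenotypic
#' noise, using the compiled engine. Per generation: one Metropolis-Hastings
#' update of the environmental perturbation per input; phenotype and fitness
#' realization (allele sums, environmental shift, developmental noise);
#' fitness-proportional parent sampling by rejection (two distinct parents
#' per offspring); transmission with recombination; mutation with the allele
#' cap. Populations are sampled at a fixed cadence after burn-in.
#'
#' All randomness flows from `seed`; identical seeds give identical
#' snapshot streams.
#'
#' @param landscape A `ridge_landscape` (not a custom R-function landscape).
#' @param config A [sim_config()].
#' @param seed Integer seed (optional; the current RNG state is used if
#'   omitted).
#' @param init Optional starting `allele_table` (default:
#'   [init_population()] at the ridge corner).
#' @param track_rarest Record each sampled individual's rarest-allele
#'   population frequency (small extra cost).
#' @return A `ridge_sim` object with elements `snapshots` (tibble: one row
#'   per individual per sampled generation with nominal `x_*`, heritable
#'   `xh_*` and effective `xe_*` inputs, phenotypes `z`, `z_h`, fitness `w`
#'   and `rarest_freq`), `env` (sampled environmental perturbations),
#'   `final` (final `allele_table`), `config`, `landscape`.
#' @examples
#' land <- landscape_lp(k = 0)
#' cfg <- sim_config(N = 100, generations = 2000, burn_in = 500,
#'                   sample_every = 500, sigma_dev = 0.05, sigma_env = 0.05)
#' sim <- run_simulation(land, cfg, seed = 1)
#' glance(sim)
#' @export
run_simulation <- function(landscape, config = sim_config(), seed = NULL,
                           init = NULL, track_rarest = TRUE) {
  stopifnot(inherits(landscape, "ridge_landscape"),
            inherits(config, "sim_config"))
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    init <- init_population(landscape, config$N, config$z_opt,
                            config$start_inputs)
  }
  stopifnot(inherits(init, "allele_table"))
  d <- dim(init$values)[2]
  if (d != landscape$d) abort("allele table loci do not match landscape inputs")
  N <- dim(init$values)[1]
  if (N != config$N) abort("allele table size does not match config N")
  if (any(init$values >= config$allele_cap)) {
    abort("initial allele values must lie below allele_cap")
  }

  # engine layout: columns l1c1 l1c2 l2c1 l2c2 ...
  av <- matrix(0, N, 2 * d)
  lv <- matrix(0L, N, 2 * d)
  for (l in seq_len(d)) {
    av[, 2 * l - 1] <- init$values[, l, 1]
    av[, 2 * l] <- init$values[, l, 2]
    lv[, 2 * l - 1] <- init$lineage[, l, 1]
    lv[, 2 * l] <- init$lineage[, l, 2]
  }

  cfg <- list(N = N, d = d, mu = config$mu, sigma_mu = config$sigma_mu,
              recomb = config$recomb, allele_cap = config$allele_cap,
              generations = config$generations, burn_in = config$burn_in,
              sample_every = config$sample_every,
              sigma_dev = config$sigma_dev, sigma_env = config$sigma_env,
              sigma_step = config$sigma_step_ratio * config$sigma_env,
              s = config$s, z_opt = config$z_opt,
              track_rarest = isTRUE(track_rarest),
              next_lineage = init$next_lineage)

  res <- cpp_simulate(av, lv, cfg, landscape_cpp_spec(landscape))

  n_snap <- length(res$snap_gen)
  snap <- as.data.frame(res$snap_ind)
  names(snap) <- c(paste0("x_", seq_len(d)), paste0("xh_", seq_len(d)),
                   paste0("xe_", seq_len(d)), "z", "z_h", "w", "rarest_freq")
  snap <- tibble(
    generation = rep(res$snap_gen, each = N),
    id = rep(seq_len(N), times = n_snap),
    !!!snap
  )
  env <- as.data.frame(res$snap_delta)
  names(env) <- paste0("delta_", seq_len(d))
  env <- tibble(generation = res$snap_gen, !!!env)

  fin_vals <- array(0, dim = c(N, d, 2))
  fin_lins <- array(0L, dim = c(N, d, 2))
  for (l in seq_len(d)) {
    fin_vals[, l, 1] <- res$alleles[, 2 * l - 1]
    fin_vals[, l, 2] <- res$alleles[, 2 * l]
    fin_lins[, l, 1] <- res$lineage[, 2 * l - 1]
    fin_lins[, l, 2] <- res$lineage[, 2 * l]
  }

  structure(
    list(snapshots = snap, env = env,
         final = allele_table(fin_vals, fin_lins,
                              next_lineage = res$next_lineage),
         config = config, landscape = landscape, seed = seed),
    class = "ridge_sim"
  )
}

#' @export
print.ridge_sim <- function(x, ...) {
  cat(sprintf(
    "<ridge_sim> N = %d, %g generations, %d sampled time points\n",
    x$config$N, x$config$generations,
    length(unique(x$snapshots$generation))
  ))
  invisible(x)
}

#' @export
tidy.ridge_sim <- function(x, ...) x$snapshots

#' @export
glance.ridge_sim <- function(x, ...) {
  sn <- x$snapshots
  per <- dplyr::summarise(
    dplyr::group_by(sn, .data$generation),
    mean_z = mean(.data$z), mean_w = mean(.data$w), .groups = "drop"
  )
  loc <- corner_localization(x)
  tibble(
    n_time_points = nrow(per),
    mean_z = mean(per$mean_z),
    mean_w = mean(per$mean_w),
    median_ratio = median(loc$ratios$ratio)
  )
}

#' Corner localization of a simulated population
#'
#' For each sampled time point, the population-mean nominal input values and
#' their folded ratio (largest mean input over smallest, so the ratio is
#' always `>= 1` and invariant to relabelling loci); the ratio is 1 exactly
#' at the ridge corner. The summary reports, for each bound, the fraction of
#' time points whose ratio lies within it (presets 1.2, 1.4 and 3.0).
#'
#' @param x A `ridge_sim` or a snapshot tibble with `generation` and
#'   nominal input columns `x_*`.
#' @param bounds Ratio bounds to report fractions for.
#' @return A `corner_localization` object: `ratios` (per time point) and
#'   `fractions` (per bound); `tidy()` returns the former, `glance()` the
#'   latter in wide form.
#' @export
corner_localization <- function(x, bounds = c(1.2, 1.4, 3.0)) {
  sn <- if (inherits(x, "ridge_sim")) x$snapshots else as_tibble(x)
  xcols <- grep("^x_[0-9]+$", names(sn), value = TRUE)
  stopifnot(length(xcols) >= 2, "generation" %in% names(sn))
  per <- dplyr::summarise(
    dplyr::group_by(sn, .data$generation),
    dplyr::across(dplyr::all_of(xcols), mean),
    .groups = "drop"
  )
  m <- as.matrix(per[xcols])
  per$ratio <- apply(m, 1, max) / apply(m, 1, min)
  fr <- tibble(
    bound = bounds,
    fraction = vapply(bounds, function(b) mean(per$ratio <= b), 0)
  )
  structure(list(ratios = per, fractions = fr),
            class = "corner_localization")
}

#' @export
print.corner_localization <- function(x, ...) {
  cat("<corner_localization>", nrow(x$ratios), "time points\n")
  print(x$fractions)
  invisible(x)
}

#' @export
tidy.corner_localization <- function(x, ...) x$ratios

#' @export
glance.corner_localization <- function(x, ...) {
  wide <- setNames(as.list(x$fractions$fraction),
                   paste0("within_", x$fractions$bound))
  tibble(!!!wide, median_ratio = median(x$ratios$ratio))
}
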