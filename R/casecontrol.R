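#' Case and control sampling from a population snapshot
#'
#' `sample_cases()` returns the individuals in the top `fraction` of
#' phenotype values (`ceiling(fraction * n)` individuals, ties broken by
#' stable index order) — the "common disease" class, default prevalence 1%.
#' `sample_controls()` draws `count` individuals uniformly without
#' replacement from the phenotype window between the given rank percentiles
#' (default the 25th-75th, i.e. the typical middle half of the population).
#'
#' @param snapshot A tibble with one row per individual for a single time
#'   point, containing at least a phenotype column `z`.
#' @param fraction Case fraction of the population, in `(0, 0.5)`.
#' @param count Number of controls.
#' @param window Length-2 rank-percentile window for controls.
#' @return The selected rows of `snapshot`.
#' @export
sample_cases <- function(snapshot, fraction = 0.01) {
  stopifnot(fraction > 0, fraction < 0.5, "z" %in% names(snapshot))
  n <- nrow(snapshot)
  m <- ceiling(fraction * n)
  ord <- order(-snapshot$z, seq_len(n))
  snapshot[sort(ord[seq_len(m)]), ]
}

#' @rdname sample_cases
#' @export
sample_controls <- function(snapshot, count = 500, window = c(0.25, 0.75)) {
  stopifnot(length(window) == 2, window[1] >= 0, window[2] <= 1,
            window[1] < window[2], "z" %in% names(snapshot))
  n <- nrow(snapshot)
  r <- rank(snapshot$z, ties.method = "first")
  in_window <- r > window[1] * n & r <= window[2] * n
  if (window[1] == 0) in_window <- in_window | r == min(r)
  pool <- which(in_window)
  if (length(pool) < count) {
    abort(sprintf("control window holds %d individuals, fewer than count = %d",
                  length(pool), count))
  }
  snapshot[sort(sample(pool, count)), ]
}

#' Control reference point and phenotype
#'
#' The hypothetical "typical healthy" genotype: the coordinate-wise median
#' of the controls' effective input values (i.e. including developmental
#' noise), and the landscape phenotype `z_controls` at that point. Case
#' phenotype deviations are partitioned relative to this reference.
#'
#' @param controls Control rows with effective input columns `xe_*` (or
#'   `nominal = TRUE` to use nominal inputs `x_*` instead).
#' @param landscape A `ridge_landscape`.
#' @param nominal Use nominal rather than effective inputs (off by
#'   default).
#' @return A list with `inputs` (length-`d` median point) and `z`.
#' @export
control_reference <- function(controls, landscape, nominal = FALSE) {
  stopifnot(nrow(controls) > 0)
  prefix <- if (nominal) "^x_[0-9]+$" else "^xe_[0-9]+$"
  cols <- grep(prefix, names(controls), value = TRUE)
  stopifnot(length(cols) == landscape$d)
  med <- vapply(controls[cols], median, 0)
  list(inputs = med, z = unname(eval_landscape(landscape, t(med))))
}

#' Fitness relative to the control sample
#'
#' Each case's fitness divided by the mean fitness of the controls. Values
#' above 1 are possible (e.g. under environmental noise the control class
#' may sit off the optimum while the top-phenotype class is nearer to it).
#'
#' @param case_w Case fitness values.
#' @param control_w Control fitness values.
#' @return Numeric vector of relative fitness values.
#' @export
relative_fitness <- function(case_w, control_w) {
  if (length(control_w) == 0) abort("control sample is empty")
  mw <- mean(control_w)
  if (mw == 0) abort("mean control fitness is zero")
  case_w / mw
}

#' Per-case epistasis and fitness report across sampled time points
#'
#' The full case-control analysis of a simulation: at every sampled time
#' point, takes the top-phenotype cases and a random control sample,
#' computes the control reference ([control_reference()]), each case's
#' fitness relative to mean control fitness, and the heritable / additive /
#' epistatic partition of its phenotype deviation ([partition_case()]).
#'
#' Transient interventions are assessment-only: they change the phenotypes
#' and fitness used in the report without feeding back into the evolving
#' population. `s_prime` re-evaluates fitness under an abruptly increased
#' selection strength; `delta_env` shifts every log input by a fixed amount
#' before phenotypes are recomputed.
#'
#' @param sim A `ridge_sim`.
#' @param case_fraction Top phenotype fraction treated as cases.
#' @param n_controls Number of controls per time point.
#' @param window Control rank-percentile window.
#' @param s_prime Optional transient selection strength replacing `s`.
#' @param delta_env Optional transient log-scale environmental shift.
#' @param nominal_reference Use nominal instead of effective inputs for the
#'   control reference.
#' @return A tibble with one row per case per time point: `generation`,
#'   `id`, `z`, `z_h`, `w`, `z_controls`, `relative_fitness`, `H_ind`,
#'   `h_ind`, `epistatic_fraction`, `degenerate`, `rarest_freq`.
#' @examples
#' land <- landscape_lp(k = 0)
#' cfg <- sim_config(N = 200, generations = 4000, burn_in = 1000,
#'                   sample_every = 1000, sigma_dev = 0.05, sigma_env = 0.05)
#' sim <- run_simulation(land, cfg, seed = 1)
#' rep <- case_control_report(sim, n_controls = 50)
#' case_summary(rep)
#' @export
case_control_report <- function(sim, case_fraction = 0.01, n_controls = 500,
                                window = c(0.25, 0.75), s_prime = NULL,
                                delta_env = 0,
                                nominal_reference = FALSE) {
  stopifnot(inherits(sim, "ridge_sim"))
  landscape <- sim$landscape
  d <- landscape$d
  s_eff <- if (is.null(s_prime)) sim$config$s else s_prime
  xe_cols <- paste0("xe_", seq_len(d))
  xh_cols <- paste0("xh_", seq_len(d))

  one_point <- function(snap1) {
    if (delta_env != 0) {
      snap1[xe_cols] <- apply_env_shift(snap1[xe_cols], delta_env)
      snap1[xh_cols] <- apply_env_shift(snap1[xh_cols], delta_env)
      snap1$z <- eval_landscape(landscape, as.matrix(snap1[xe_cols]))
      snap1$z_h <- eval_landscape(landscape, as.matrix(snap1[xh_cols]))
    }
    snap1$w <- fitness(snap1$z, s_eff, sim$config$z_opt)
    cases <- sample_cases(snap1, case_fraction)
    controls <- sample_controls(snap1, n_controls, window)
    ref <- control_reference(controls, landscape, nominal = nominal_reference)
    part <- partition_case(landscape, cases$z, cases$z_h,
                           as.matrix(cases[xh_cols]), ref)
    tibble(
      generation = cases$generation, id = cases$id, z = cases$z,
      z_h = cases$z_h, w = cases$w, z_controls = ref$z,
      relative_fitness = relative_fitness(cases$w, controls$w),
      H_ind = part$H_ind, h_ind = part$h_ind,
      epistatic_fraction = part$epistatic_fraction,
      degenerate = part$degenerate,
      rarest_freq = cases$rarest_freq
    )
  }

  pieces <- lapply(split(sim$snapshots, sim$snapshots$generation), one_point)
  out <- dplyr::bind_rows(pieces)
  out[order(out$generation, out$id), ]
}

#' Per-time-point summary of a case-control report
#'
#' Aggregates a [case_control_report()] by time point: mean case relative
#' fitness, mean epistatic fraction over all cases and over "unfit" cases
#' (relative fitness below `unfit_threshold`), and bookkeeping counts
#' (including degenerate cases excluded from the partition).
#'
#' @param report Output of [case_control_report()].
#' @param unfit_threshold Relative-fitness threshold defining unfit cases
#'   (default 0.9; 0.75 is the preset for the severe class).
#' @return One row per time point.
#' @export
case_summary <- function(report, unfit_threshold = 0.9) {
  dplyr::summarise(
    dplyr::group_by(report, .data$generation),
    n_cases = dplyr::n(),
    n_excluded = sum(.data$degenerate),
    mean_relative_fitness = mean(.data$relative_fitness),
    mean_epistatic_fraction = mean(.data$epistatic_fraction, na.rm = TRUE),
    n_unfit = sum(.data$relative_fitness < unfit_threshold, na.rm = TRUE),
    mean_epistatic_fraction_unfit = mean(
      .data$epistatic_fraction[.data$relative_fitness < unfit_threshold],
      na.rm = TRUE
    ),
    median_rarest_freq_unfit = median(
      .data$rarest_freq[.data$relative_fitness < unfit_threshold],
      na.rm = TRUE
    ),
    .groups = "drop"
  )
}
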