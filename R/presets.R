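#' Scenario presets
#'
#' Named bundles of landscape, noise, population-genetic and case-control
#' settings reproducing the study regimes explored in this package. Every
#' preset fully determines a run given a seed; [run_scenario()] executes one
#' (optionally scaled down) and writes its artifacts.
#'
#' @return `preset_list()`: a tibble naming the presets;
#'   `scenario_preset()`: the configuration list for one preset.
#' @export
preset_list <- function() {
  tibble(
    name = names(.presets),
    description = vapply(.presets, function(p) p$description, "")
  )
}

#' @rdname preset_list
#' @param name Preset name (see [preset_list()]).
#' @export
scenario_preset <- function(name) {
  if (!name %in% names(.presets)) {
    abort(sprintf("unknown preset '%s'; see preset_list()", name))
  }
  .presets[[name]]
}

.presets <- list(
  corner_escape = list(
    description = "Simple LP (k = 0), no phenotypic noise: selection drives the population off the corner",
    landscape = list(kind = "lp", k = 0),
    sim = list(sigma_mu = 1, sigma_dev = 0, sigma_env = 0)
  ),
  corner_retention = list(
    description = "Sharp corner (k = 1e-4) with developmental noise 0.1: population held at the corner",
    landscape = list(kind = "lp", k = 1e-4),
    sim = list(sigma_mu = 1, sigma_dev = 0.1, sigma_env = 0)
  ),
  case_control_equilibrium = list(
    description = "Equilibrium case-control regime: k = 0, s = 1, sigma_dev = sigma_env = 0.05",
    landscape = list(kind = "lp", k = 0),
    sim = list(sigma_mu = 1, sigma_dev = 0.05, sigma_env = 0.05),
    casecontrol = list(case_fraction = 0.01, n_controls = 500)
  ),
  selection_shift = list(
    description = "Equilibrium regime assessed under a transient 5-fold selection increase",
    landscape = list(kind = "lp", k = 0),
    sim = list(sigma_mu = 1, sigma_dev = 0.05, sigma_env = 0.05),
    casecontrol = list(case_fraction = 0.01, n_controls = 500, s_prime = 5)
  ),
  localization_sweep = list(
    description = "Corner-localization fractions across noise levels (developmental and environmental)",
    landscape = list(kind = "lp", k = 1e-4),
    sim = list(sigma_mu = 1),
    sweep = list(parameter = "sigma_dev",
                 values = c(0, 0.025, 0.05, 0.1, 0.2))
  ),
  mutation_sweep = list(
    description = "Mutation-rate sweep at the equilibrium case-control regime",
    landscape = list(kind = "lp", k = 0),
    sim = list(sigma_mu = 1, sigma_dev = 0.05, sigma_env = 0.05),
    casecontrol = list(case_fraction = 0.01, n_controls = 500),
    sweep = list(parameter = "mu", values = c(1e-4, 1e-3))
  ),
  d_input_sweep = list(
    description = "Number-of-inputs sweep on the minimum landscape at the equilibrium regime",
    landscape = list(kind = "min"),
    sim = list(sigma_mu = 1, sigma_dev = 0.05, sigma_env = 0.05),
    casecontrol = list(case_fraction = 0.01, n_controls = 500),
    sweep = list(parameter = "d", values = 2:4)
  ),
  curve_ridge = list(
    description = "Arbitrary closed-loop ridge landscape via lookup table",
    landscape = list(
      kind = "curve_ridge",
      ln_x = "sin(2*t)*cos(2*t) - 2*cos(t)",
      ln_y = "(cosh(t) + 5*sin(t))/4",
      start_t = 2
    ),
    sim = list(sigma_mu = 1, sigma_dev = 0.05, sigma_env = 0.05)
  )
)

config_landscape <- function(spec) {
  kind <- spec$kind %||% "lp"
  switch(kind,
    lp = landscape_lp(k = spec$k %||% 0, d = spec$d %||% 2),
    min = landscape_min(d = spec$d %||% 2),
    poly = landscape_poly(n = spec$n %||% 2, xi = spec$xi %||% 0.5),
    product = landscape_product(),
    saturable = landscape_saturable(),
    curve_ridge = {
      fx <- function(t) eval(parse(text = spec$ln_x), list(t = t))
      fy <- function(t) eval(parse(text = spec$ln_y), list(t = t))
      grid_x <- seq(-3.5, 3.5, length.out = spec$nx %||% 700)
      grid_y <- seq(-2, 4, length.out = spec$ny %||% 600)
      build_lookup(curve_ridge(fx, fy), grid_ln_x = grid_x,
                   grid_ln_y = grid_y, clamp = TRUE)
    },
    abort(sprintf("unknown landscape kind '%s'", kind))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write configuration documents
#'
#' Configurations are flat JSON documents with sections `landscape`, `sim`
#' and `casecontrol`. Unknown sections or keys, and out-of-range values,
#' raise descriptive validation errors; an empty document yields the full
#' defaults of [sim_config()]. `load_config(write_config(cfg, path))` is the
#' identity.
#'
#' @param path File path of a JSON configuration.
#' @param config A configuration list as returned by `load_config()` or
#'   [scenario_preset()].
#' @return `load_config()`: the validated configuration list.
#' @export
load_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

#' @rdname load_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

validate_config <- function(cfg) {
  allowed <- c("landscape", "sim", "casecontrol", "sweep", "description")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra)) {
    abort(paste0("unknown configuration section(s): ",
                 paste(extra, collapse = ", ")))
  }
  sim_keys <- names(formals(sim_config))
  extra <- setdiff(names(cfg$sim), c(sim_keys, "d"))
  if (length(extra)) {
    abort(paste0("unknown sim key(s): ", paste(extra, collapse = ", ")))
  }
  cc_keys <- c("case_fraction", "n_controls", "window", "s_prime",
               "delta_env", "unfit_threshold")
  extra <- setdiff(names(cfg$casecontrol), cc_keys)
  if (length(extra)) {
    abort(paste0("unknown casecontrol key(s): ", paste(extra, collapse = ", ")))
  }
  # range validation via the constructor
  do.call(sim_config, cfg$sim[setdiff(names(cfg$sim), "d")] %||% list())
  cfg
}

#' Execute a scenario and write its artifacts
#'
#' Runs a preset (or an explicit configuration) at a given seed, writing
#' tab-separated outputs and a JSON manifest into `out_dir`: population
#' snapshots (`snapshots.tsv`), environmental perturbations (`env.tsv`),
#' the per-case report (`cases.tsv`) and its per-time-point summary
#' (`case_summary.tsv`) when case-control settings are present, and
#' `manifest.json` recording every parameter, the seed and the package
#' version needed to re-run. A `scale` factor below 1 proportionally
#' reduces the population size and all generation counts (with a warning),
#' for desk-scale replicas of the full-scale regimes. Sweep presets write
#' one subdirectory per swept value. Identical seeds give byte-identical
#' outputs.
#'
#' @param preset A preset name or a configuration list.
#' @param seed Integer seed.
#' @param scale Scale factor in `(0, 1]` applied to `N`, `generations`,
#'   `burn_in` and `sample_every`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_scenario <- function(preset, seed, scale = 1, out_dir) {
  cfg <- if (is.character(preset)) scenario_preset(preset) else validate_config(preset)
  stopifnot(scale > 0, scale <= 1)
  if (!is.null(cfg$sweep)) {
    vals <- cfg$sweep$values
    out <- vector("list", length(vals))
    for (i in seq_along(vals)) {
      sub <- cfg
      sub$sweep <- NULL
      if (cfg$sweep$parameter == "d") {
        sub$landscape$d <- vals[i]
      } else {
        sub$sim[[cfg$sweep$parameter]] <- vals[i]
      }
      out[[i]] <- run_scenario(
        sub, seed = seed + i - 1, scale = scale,
        out_dir = file.path(out_dir, paste0(cfg$sweep$parameter, "_", vals[i]))
      )
    }
    return(invisible(out))
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_args <- cfg$sim %||% list()
  d <- sim_args$d %||% cfg$landscape$d %||% 2
  cfg$landscape$d <- d
  sim_args$d <- NULL
  config <- do.call(sim_config, sim_args)
  if (scale < 1) {
    warn(sprintf("scaling N and generation counts by %g", scale))
    config$N <- max(2L, as.integer(round(config$N * scale)))
    config$generations <- max(2, round(config$generations * scale))
    config$burn_in <- round(config$burn_in * scale)
    config$sample_every <- max(1, round(config$sample_every * scale))
  }
  landscape <- config_landscape(cfg$landscape)
  if (identical(cfg$landscape$kind, "curve_ridge")) {
    t0 <- cfg$landscape$start_t %||% 0
    crv <- landscape$curve
    config$start_inputs <- exp(c(crv$ln_x(t0), crv$ln_y(t0)))
  }
  sim <- run_simulation(landscape, config, seed = seed)

  write_tsv <- function(x, file) {
    utils::write.table(x, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(sim$snapshots, "snapshots.tsv")
  write_tsv(sim$env, "env.tsv")

  if (!is.null(cfg$casecontrol)) {
    cc <- cfg$casecontrol
    rep <- case_control_report(
      sim,
      case_fraction = cc$case_fraction %||% 0.01,
      n_controls = min(cc$n_controls %||% 500, floor(config$N / 2)),
      s_prime = cc$s_prime,
      delta_env = cc$delta_env %||% 0
    )
    write_tsv(rep, "cases.tsv")
    write_tsv(case_summary(rep, cc$unfit_threshold %||% 0.9),
              "case_summary.tsv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ridgesim")),
    seed = seed, scale = scale, config = unclass(config),
    landscape = cfg$landscape, casecontrol = cfg$casecontrol,
    description = cfg$description
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
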