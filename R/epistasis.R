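#' Functional epistasis of a genotype relative to a reference
#'
#' The additive fraction `h*` of the phenotypic difference between a target
#' genotype and a reference genotype:
#' \deqn{h^* = \frac{\sum_i \left[Z(\ldots, x_i, \ldots)|_{ref} - Z(ref)\right]}
#'                  {Z(target) - Z(ref)},}
#' where the numerator sums, over loci, the phenotype deviations of the
#' single-substitution genotypes (one target input substituted into the
#' reference). `1 - h*` is the functional epistasis; `h* < 1` is synergistic
#' (combined effect exceeds the sum of single effects), `h* > 1`
#' antagonistic.
#'
#' @param landscape A `ridge_landscape`.
#' @param target,reference Input-value vectors of length `d`, or matrices /
#'   data frames with `d` columns (row-wise pairs; a single reference row is
#'   recycled).
#' @return Numeric vector of `h*` values; `NA` where the full phenotype
#'   deviation `Z(target) - Z(reference)` vanishes (flagged with a warning).
#' @examples
#' m <- landscape_min()
#' functional_epistasis(m, c(2, 2), c(1, 1)) # 0: pure synergy
#' functional_epistasis(m, c(0.5, 0.5), c(1, 1)) # 2: antagonistic
#' @export
functional_epistasis <- function(landscape, target, reference) {
  d <- landscape$d
  tgt <- as_input_matrix(target, d)
  ref <- as_input_matrix(reference, d)
  if (nrow(ref) == 1 && nrow(tgt) > 1) {
    ref <- ref[rep(1, nrow(tgt)), , drop = FALSE]
  }
  stopifnot(nrow(ref) == nrow(tgt))
  zt <- eval_landscape(landscape, tgt)
  zr <- eval_landscape(landscape, ref)
  denom <- zt - zr
  num <- 0
  for (i in seq_len(d)) {
    single <- ref
    single[, i] <- tgt[, i]
    num <- num + (eval_landscape(landscape, single) - zr)
  }
  bad <- denom == 0
  if (any(bad)) {
    warn(sprintf("%d pair(s) with zero phenotype deviation; h* undefined", sum(bad)))
  }
  ifelse(bad, NA_real_, num / denom)
}

#' Heritable / additive / epistatic partition of case phenotypes
#'
#' Decomposes, for each case individual, its phenotypic deviation from the
#' control reference into a heritable fraction
#' \deqn{H_{ind} = \frac{z_H - z_{controls}}{z_{case} - z_{controls}},}
#' an additive fraction
#' \deqn{h_{ind} = \frac{\sum_i (z_i - z_{controls})}{z_{case} - z_{controls}},}
#' and the epistatic fraction `H_ind - h_ind`. Here `z_case` is the observed
#' (noise-inclusive) phenotype, `z_H` the heritable phenotype (computed from
#' the case's input values before developmental noise), `z_controls` the
#' phenotype at the median effective inputs of the controls, and `z_i` the
#' single-mutant phenotypes obtained by substituting the case's i-th
#' heritable input into the control reference coordinates.
#'
#' With developmental noise off, `H_ind = 1` exactly and `h_ind` equals the
#' functional `h*` of [functional_epistasis()].
#'
#' @param landscape A `ridge_landscape`.
#' @param z_case Observed case phenotypes.
#' @param z_h Heritable case phenotypes (before developmental noise).
#' @param heritable_inputs Matrix / data frame of case heritable input
#'   values, `d` columns.
#' @param control_ref A control reference from [control_reference()] (or any
#'   list with elements `inputs` and `z`).
#' @param tol Cases with `|z_case - z_controls| <= tol` are degenerate: they
#'   get `NA` fractions and `degenerate = TRUE` so callers can count
#'   exclusions.
#' @return A tibble with columns `H_ind`, `h_ind`, `epistatic_fraction` and
#'   `degenerate`.
#' @export
partition_case <- function(landscape, z_case, z_h, heritable_inputs,
                           control_ref, tol = 1e-12) {
  d <- landscape$d
  hin <- as_input_matrix(heritable_inputs, d)
  stopifnot(length(z_case) == nrow(hin), length(z_h) == nrow(hin))
  zc <- control_ref$z
  ref <- control_ref$inputs
  stopifnot(length(ref) == d)
  denom <- z_case - zc
  degenerate <- abs(denom) <= tol
  H <- (z_h - zc) / denom
  num <- 0
  for (i in seq_len(d)) {
    single <- matrix(ref, nrow(hin), d, byrow = TRUE)
    single[, i] <- hin[, i]
    num <- num + (eval_landscape(landscape, single) - zc)
  }
  h <- num / denom
  H[degenerate] <- NA_real_
  h[degenerate] <- NA_real_
  tibble(H_ind = H, h_ind = h, epistatic_fraction = H - h,
         degenerate = degenerate)
}

#' Statistical (narrow-sense) heritability by linear regression
#'
#' The fraction of phenotypic variance explained by the best linear model in
#' the input values, `h_pop^2 = sigma_A^2 / sigma^2`, computed as the R^2 of
#' an ordinary (or weighted) least-squares regression of phenotype on the
#' `d` input values. When non-genetic variance is absent, `1 - h_pop^2` is
#' the statistical epistasis of the sample.
#'
#' `case_enriched_heritability()` recomputes the same quantity under a
#' case-control ascertainment design: individuals in the top
#' `case_fraction` of phenotype values are importance-reweighted so that
#' they carry a total weight share of `enrichment` (e.g. 0.5 for a balanced
#' case-control study), everyone else sharing the rest uniformly. When
#' `enrichment` equals the natural prevalence the weights are uniform and
#' the two estimators coincide.
#'
#' @param data Data frame containing the phenotype and input columns.
#' @param phenotype Name of the phenotype column (default `"z"`).
#' @param inputs Character vector of input-value column names (predictors).
#' @param case_fraction Top phenotype fraction treated as cases.
#' @param enrichment Target share of total regression weight carried by the
#'   case class, in `(0, 0.5]` typically.
#' @return An object of class `heritability_fit`; `glance()` gives a
#'   one-row tibble with `h2`, `n` and `weighted`, `tidy()` the regression
#'   coefficients.
#' @examples
#' dat <- tibble::tibble(x = runif(200, 0.5, 2), y = runif(200, 0.5, 2))
#' dat$z <- phenotype(landscape_min(), dat[c("x", "y")])
#' glance(statistical_heritability(dat, inputs = c("x", "y")))
#' @export
statistical_heritability <- function(data, phenotype = "z",
                                     inputs = c("x", "y")) {
  heritability_fit(data, phenotype, inputs, weights = NULL)
}

#' @rdname statistical_heritability
#' @export
case_enriched_heritability <- function(data, phenotype = "z",
                                       inputs = c("x", "y"),
                                       case_fraction = 0.01,
                                       enrichment = 0.5) {
  stopifnot(case_fraction > 0, case_fraction <= 0.5,
            enrichment > 0, enrichment < 1)
  z <- data[[phenotype]]
  n <- length(z)
  n_case <- ceiling(case_fraction * n)
  if (n_case < 1) abort("no cases in sample")
  thr <- sort(z, decreasing = TRUE)[n_case]
  is_case <- z >= thr
  share <- mean(is_case)
  w <- ifelse(is_case, enrichment / share, (1 - enrichment) / (1 - share))
  heritability_fit(data, phenotype, inputs, weights = w)
}

heritability_fit <- function(data, phenotype, inputs, weights) {
  stopifnot(phenotype %in% names(data), all(inputs %in% names(data)))
  df <- as.data.frame(data[c(phenotype, inputs)])
  names(df)[1] <- ".z"
  if (nrow(df) <= length(inputs) + 1) {
    abort("sample size must exceed the number of loci + 1")
  }
  w <- if (is.null(weights)) rep(1, nrow(df)) else weights
  zvar <- sum(w * (df$.z - sum(w * df$.z) / sum(w))^2)
  if (zvar == 0) abort("phenotypic variance is zero; heritability undefined")
  fit <- lm(.z ~ ., data = df, weights = w)
  res <- sum(w * fit$residuals^2)
  h2 <- max(0, min(1, 1 - res / zvar))
  structure(
    list(h2 = h2, fit = fit, n = nrow(df),
         weighted = !is.null(weights)),
    class = "heritability_fit"
  )
}

#' @export
print.heritability_fit <- function(x, ...) {
  cat(sprintf("Additive heritability h2 = %.4f (n = %d%s)\n", x$h2, x$n,
              if (x$weighted) ", weighted" else ""))
  invisible(x)
}

#' @export
glance.heritability_fit <- function(x, ...) {
  tibble(h2 = x$h2, statistical_epistasis = 1 - x$h2, n = x$n,
         weighted = x$weighted)
}

#' @export
tidy.heritability_fit <- function(x, ...) {
  co <- coef(x$fit)
  tibble(term = names(co), estimate = unname(co))
}
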