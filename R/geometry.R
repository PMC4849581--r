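#' Orientation and curvature of iso-phenotype contours
#'
#' Computes, at each query point, the local geometry of the phenotype contour
#' passing through it, from central finite differences of `ln z` with respect
#' to `(ln x, ln y)`. Orientation is the slope of the contour in the
#' `(ln x, ln y)` plane (also reported as an angle in degrees, in
#' `(-90, 90]`); curvature is the inverse radius of curvature of the contour
#' (always non-negative). Ridge corners are points of high contour curvature;
#' orientation decides whether variation at both loci contributes to the
#' phenotype (diagonal orientation) or effectively only one (axis-parallel).
#'
#' @param landscape A `ridge_landscape`.
#' @param data Data frame with columns `ln_x` and `ln_y` (query points).
#' @param h Finite-difference step on the log scale.
#' @param tol Gradient norm below which the contour direction is undefined;
#'   such points are flagged `degenerate` and get `NA` geometry.
#' @return `data` with columns `slope`, `orientation` (degrees), `curvature`
#'   and `degenerate` added.
#' @examples
#' pts <- tibble::tibble(ln_x = c(2, 0), ln_y = c(0, 2))
#' contour_geometry(landscape_lp(k = 0.01), pts)
#' @export
contour_geometry <- function(landscape, data, h = 1e-3, tol = 1e-8) {
  stopifnot(all(c("ln_x", "ln_y") %in% names(data)))
  u <- data$ln_x
  v <- data$ln_y
  F <- function(uu, vv) log(eval_landscape(landscape, cbind(exp(uu), exp(vv))))
  f0 <- F(u, v)
  fpu <- F(u + h, v); fmu <- F(u - h, v)
  fpv <- F(u, v + h); fmv <- F(u, v - h)
  fpp <- F(u + h, v + h); fpm <- F(u + h, v - h)
  fmp <- F(u - h, v + h); fmm <- F(u - h, v - h)
  Fu <- (fpu - fmu) / (2 * h)
  Fv <- (fpv - fmv) / (2 * h)
  Fuu <- (fpu - 2 * f0 + fmu) / h^2
  Fvv <- (fpv - 2 * f0 + fmv) / h^2
  Fuv <- (fpp - fpm - fmp + fmm) / (4 * h^2)
  gn2 <- Fu^2 + Fv^2
  degenerate <- gn2 < tol^2
  slope <- ifelse(degenerate, NA_real_, -Fu / Fv)
  ang <- atan2(-Fu, Fv) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90
  ang[ang == -90] <- 90
  orientation <- ifelse(degenerate, NA_real_, ang)
  curvature <- ifelse(
    degenerate, NA_real_,
    abs(Fu^2 * Fvv - 2 * Fu * Fv * Fuv + Fv^2 * Fuu) / gn2^1.5
  )
  if (any(degenerate)) {
    warn(sprintf(
      "%d point(s) have a vanishing phenotype gradient; geometry undefined there",
      sum(degenerate)
    ))
  }
  dplyr::mutate(as_tibble(data), slope = slope, orientation = orientation,
                curvature = curvature, degenerate = degenerate)
}

#' Maximum local epistasis over paired mutational perturbations
#'
#' For each query point, taken as the reference genotype, enumerates the
#' eight signed perturbation directions obtained by moving each log input by
#' `-step`, `0`, or `+step` (excluding the null move) and returns the largest
#' `|1 - h*|`, where `h*` is the additive fraction of the phenotype change
#' ([functional_epistasis()]). This is a gridded upper envelope of the local
#' functional epistasis attainable with mutations of effect size `step`; it
#' is maximal at sharp, diagonally oriented ridge corners and vanishes on
#' linear landscapes.
#'
#' @param landscape A `ridge_landscape` with two inputs.
#' @param data Data frame with columns `ln_x`, `ln_y`.
#' @param step Log-scale perturbation radius (default 0.3).
#' @param tol Phenotype changes smaller than `tol` (relative to the reference
#'   phenotype) leave that direction undefined; points where every direction
#'   is undefined get `NA`.
#' @return `data` with a `max_epistasis` column added.
#' @export
max_epistasis_map <- function(landscape, data, step = 0.3, tol = 1e-9) {
  stopifnot(all(c("ln_x", "ln_y") %in% names(data)), step > 0,
            landscape$d == 2)
  u <- data$ln_x
  v <- data$ln_y
  ref <- cbind(exp(u), exp(v))
  z0 <- eval_landscape(landscape, ref)
  best <- rep(NA_real_, length(u))
  dirs <- expand.grid(du = c(-1L, 0L, 1L), dv = c(-1L, 0L, 1L))
  dirs <- dirs[dirs$du != 0L | dirs$dv != 0L, ]
  for (r in seq_len(nrow(dirs))) {
    tgt <- cbind(exp(u + dirs$du[r] * step), exp(v + dirs$dv[r] * step))
    zt <- eval_landscape(landscape, tgt)
    ok <- abs(zt - z0) > tol * pmax(abs(z0), 1e-300)
    if (!any(ok)) next
    hstar <- functional_epistasis(landscape, tgt[ok, , drop = FALSE],
                                  ref[ok, , drop = FALSE])
    val <- abs(1 - hstar)
    cur <- best[ok]
    best[ok] <- pmax(cur, val, na.rm = TRUE)
  }
  dplyr::mutate(as_tibble(data), max_epistasis = best)
}
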