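#' Arbitrary ridge landscapes from a parametric optimal-phenotype curve
#'
#' `curve_ridge()` describes a fitness ridge whose optimal-phenotype contour
#' (`z = z_opt`) is an arbitrary parametric curve
#' `t -> (ln x(t), ln y(t))`, `t` in `t_range`. `build_lookup()` turns the
#' description into a gridded lookup landscape: at every grid node the log
#' phenotype is set to the signed shortest distance `d` to the curve,
#' `ln z = -d` outside (or everywhere, for open curves) and `ln z = +d`
#' inside a closed curve, optionally divided by a fall-off scale `f(t*) >= 1`
#' evaluated at the nearest curve parameter `t*` (larger `f` spreads the
#' fitness contours, flattening the ridge locally).
#'
#' The curve is discretized densely (`n_curve` samples, at least 10^4) and
#' nearest points found by a two-stage scan; the discretization is fine
#' enough that doubling `n_curve` changes distances by less than 1e-4 for
#' smooth curves.
#'
#' @param ln_x,ln_y Vectorized functions of the curve parameter `t` returning
#'   the log input values on the optimal contour.
#' @param t_range Length-2 numeric range of the curve parameter.
#' @param closed Logical: does the curve close on itself? Inside/outside
#'   signing of `ln z` is only available for closed curves.
#' @param falloff Optional vectorized function `f(t) >= 1` scaling distances.
#' @param n_curve Number of curve samples used for the nearest-point search.
#' @param object A `curve_ridge` description.
#' @param grid_ln_x,grid_ln_y Grid node positions in `ln x` and `ln y`. The
#'   defaults are 2100 values of `ln x` from -3.5 to 3.5 and 1800 values of
#'   `ln y` from -2 to 4.
#' @param clamp Logical: clamp out-of-bounds queries to the grid edge instead
#'   of raising an error (the default errors, since silent extrapolation
#'   distorts fitness at extreme genotypes).
#'
#' @return `curve_ridge()` returns a description object; `build_lookup()`
#'   returns a `lookup_landscape` (a `ridge_landscape` usable everywhere a
#'   landscape is accepted, including the compiled simulation engine).
#' @examples
#' ring <- curve_ridge(function(t) cos(t), function(t) sin(t), n_curve = 2e4)
#' land <- build_lookup(ring,
#'   grid_ln_x = seq(-2, 2, length.out = 201),
#'   grid_ln_y = seq(-2, 2, length.out = 201)
#' )
#' phenotype(land, c(exp(1), 1)) # on the ring: z = 1
#' @export
curve_ridge <- function(ln_x, ln_y, t_range = c(-pi, pi), closed = TRUE,
                        falloff = NULL, n_curve = 2e4) {
  stopifnot(is.function(ln_x), is.function(ln_y), length(t_range) == 2,
            n_curve >= 1e4)
  structure(
    list(ln_x = ln_x, ln_y = ln_y, t_range = t_range, closed = closed,
         falloff = falloff, n_curve = as.integer(n_curve)),
    class = "curve_ridge"
  )
}

#' @rdname curve_ridge
#' @export
build_lookup <- function(object,
                         grid_ln_x = seq(-3.5, 3.5, length.out = 2100),
                         grid_ln_y = seq(-2, 4, length.out = 1800),
                         clamp = FALSE) {
  stopifnot(inherits(object, "curve_ridge"))
  t0 <- object$t_range[1]; t1 <- object$t_range[2]
  # For closed curves drop the duplicated endpoint
  tt <- seq(t0, t1, length.out = object$n_curve + 1)
  if (object$closed) tt <- tt[-length(tt)]
  px <- object$ln_x(tt)
  py <- object$ln_y(tt)
  if (anyNA(px) || anyNA(py)) abort("curve functions produced NA values")

  near <- cpp_nearest_curve(grid_ln_x, grid_ln_y, px, py, object$closed)
  dist <- near$dist
  tstar <- tt[near$index]

  if (!is.null(object$falloff)) {
    f <- object$falloff(tstar)
    if (any(f < 1)) abort("falloff scale must satisfy f(t) >= 1")
    dist <- dist / f
  }

  if (object$closed) {
    inside <- grid_inside_curve(grid_ln_x, grid_ln_y, px, py)
    lz <- ifelse(inside, dist, -dist)
  } else {
    lz <- -dist
  }
  dim(lz) <- dim(dist)

  new_landscape(
    type = 5L, d = 2L,
    params = list(table = exp(lz), ln_x = grid_ln_x, ln_y = grid_ln_y,
                  clamp = clamp, curve = object),
    class = "lookup_landscape"
  )
}

# Even-odd (crossing-number) test for every grid node against the polygon
# formed by the curve samples, organized per grid column so the whole grid is
# classified in one pass over the edges.
grid_inside_curve <- function(gx, gy, px, py) {
  m <- length(px)
  x1 <- px; y1 <- py
  x2 <- c(px[-1], px[1]); y2 <- c(py[-1], py[1])
  inside <- matrix(FALSE, length(gx), length(gy))
  for (i in seq_along(gx)) {
    u <- gx[i]
    straddle <- (x1 <= u & x2 > u) | (x2 <= u & x1 > u)
    if (!any(straddle)) next
    f <- (u - x1[straddle]) / (x2[straddle] - x1[straddle])
    ycross <- y1[straddle] + f * (y2[straddle] - y1[straddle])
    inside[i, ] <- (findInterval(gy, sort(ycross)) %% 2L) == 1L
  }
  inside
}

#' Bilinear interpolation on a lookup landscape
#'
#' Interpolates phenotype values from the four grid nodes surrounding each
#' query point; exact at the nodes. This is the evaluation path used both
#' here and inside the compiled simulation engine.
#'
#' @param landscape A `lookup_landscape` from [build_lookup()].
#' @param ln_x,ln_y Query coordinates (log input values).
#' @return Numeric vector of phenotype values.
#' @export
interp_phenotype <- function(landscape, ln_x, ln_y) {
  stopifnot(inherits(landscape, "lookup_landscape"))
  gx <- landscape$ln_x; gy <- landscape$ln_y
  tab <- landscape$table
  fx <- (ln_x - gx[1]) / (gx[2] - gx[1])
  fy <- (ln_y - gy[1]) / (gy[2] - gy[1])
  eps <- 1e-8
  if (isTRUE(landscape$clamp)) {
    fx <- pmin(pmax(fx, 0), length(gx) - 1)
    fy <- pmin(pmax(fy, 0), length(gy) - 1)
  } else if (any(fx < -eps | fx > length(gx) - 1 + eps |
                 fy < -eps | fy > length(gy) - 1 + eps)) {
    abort("lookup query outside grid bounds (set clamp = TRUE to clamp)")
  } else {
    fx <- pmin(pmax(fx, 0), length(gx) - 1)
    fy <- pmin(pmax(fy, 0), length(gy) - 1)
  }
  i <- pmin(floor(fx), length(gx) - 2)
  j <- pmin(floor(fy), length(gy) - 2)
  u <- fx - i; v <- fy - j
  i <- i + 1L; j <- j + 1L # 1-based
  (1 - u) * (1 - v) * tab[cbind(i, j)] +
    u * (1 - v) * tab[cbind(i + 1, j)] +
    (1 - u) * v * tab[cbind(i, j + 1)] +
    u * v * tab[cbind(i + 1, j + 1)]
}
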