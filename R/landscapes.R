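#' Genotype-phenotype landscapes
#'
#' Constructors for the genotype-phenotype maps used throughout the package.
#' A landscape maps a vector of positive input values (one per locus; each
#' input is the sum of an individual's two allele values at that locus) to a
#' single phenotype value `z`.
#'
#' * `landscape_lp()` is the generalized limiting-pathway (LP) map for two
#'   inputs, \deqn{z = \tfrac12\left(k + x + y - \sqrt{(k+x+y)^2 - 4xy}\right),}
#'   where the interaction constant `k >= 0` controls how sharply the two
#'   pathways interact. At `k = 0` it reduces exactly to `min(x, y)`; large
#'   `k` corresponds to weak interaction (nearly additive behaviour near the
#'   ridge). For more than two inputs only the `k = 0` (minimum) form is
#'   defined; use `landscape_min()`.
#' * `landscape_min()` is the simple LP map `z = min(x_1, ..., x_d)` for any
#'   number of inputs `d >= 2`.
#' * `landscape_poly()` is the smooth polynomial ridge
#'   `z = x + y + (xy)^n / xi^(2n-1)`, linear along the axes and strongly
#'   non-linear beyond the crossover scale `xi`.
#' * `landscape_product()` is `z = xy/(x+y)`; `landscape_saturable()` is
#'   `z = (x/(1+x)) (y/(1+y))`. Both produce continuous fitness ridges that
#'   closely resemble the LP ridge.
#' * `landscape_custom()` wraps an arbitrary vectorized R function
#'   `fn(x_1, ..., x_d)` (mainly useful for tests and theory work; it cannot
#'   be used by the compiled simulation engine).
#'
#' @param k Interaction constant, `k >= 0` (dimensionless).
#' @param d Number of inputs (loci), integer `>= 2`.
#' @param n Positive integer exponent of the polynomial ridge.
#' @param xi Crossover scale of the polynomial ridge, `> 0`.
#' @param fn Vectorized function of `d` positive numeric vectors returning
#'   the phenotype.
#'
#' @return An object of class `ridge_landscape` (a list carrying the map type
#'   and its parameters) for use with [phenotype()], [fitness()],
#'   [run_simulation()] and the analysis functions.
#'
#' @examples
#' lp <- landscape_lp(k = 0.25)
#' phenotype(lp, c(1.5, 1.5)) # == 1 at the corner
#' phenotype(landscape_min(d = 3), c(1, 2, 3))
#' @export
landscape_lp <- function(k = 0, d = 2) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 0, d >= 2)
  d <- as.integer(d)
  if (d > 2 && k > 0) {
    abort("the generalized LP map with k > 0 is only defined for d = 2; use k = 0 (minimum) for d > 2")
  }
  if (d > 2) return(landscape_min(d))
  new_landscape(type = 0L, d = 2L, params = list(k = k),
                class = "lp_landscape")
}

#' @rdname landscape_lp
#' @export
landscape_min <- function(d = 2) {
  d <- as.integer(d)
  stopifnot(d >= 2)
  new_landscape(type = 1L, d = d, params = list(), class = "min_landscape")
}

#' @rdname landscape_lp
#' @export
landscape_poly <- function(n = 2, xi = 0.5) {
  stopifnot(n >= 1, n == round(n), xi > 0)
  new_landscape(type = 2L, d = 2L, params = list(n = n, xi = xi),
                class = "poly_landscape")
}

#' @rdname landscape_lp
#' @export
landscape_product <- function() {
  new_landscape(type = 3L, d = 2L, params = list(), class = "product_landscape")
}

#' @rdname landscape_lp
#' @export
landscape_saturable <- function() {
  new_landscape(type = 4L, d = 2L, params = list(),
                class = "saturable_landscape")
}

#' @rdname landscape_lp
#' @export
landscape_custom <- function(fn, d = 2) {
  stopifnot(is.function(fn), d >= 2)
  new_landscape(type = 99L, d = as.integer(d), params = list(fn = fn),
                class = "custom_landscape")
}

new_landscape <- function(type, d, params, class, extra = list()) {
  structure(
    c(list(type = type, d = d), params, extra),
    class = c(class, "ridge_landscape")
  )
}

#' @export
print.ridge_landscape <- function(x, ...) {
  nm <- class(x)[1]
  par <- x[setdiff(names(x), c("type", "d", "fn", "table", "curve"))]
  par <- par[vapply(par, function(p) is.numeric(p) && length(p) == 1, TRUE)]
  cat("<", nm, "> d = ", x$d, sep = "")
  if (length(par)) {
    cat(", ", paste(names(par), unlist(par), sep = " = ", collapse = ", "),
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Evaluate a landscape
#'
#' Maps positive input values to phenotype values under a landscape built by
#' one of the `landscape_*()` constructors.
#'
#' @param landscape A `ridge_landscape` object.
#' @param inputs A numeric vector of length `d` (one individual), or a matrix
#'   / data frame with `d` columns (one row per individual). All values must
#'   be positive (non-negative for the polynomial ridge, which is defined at
#'   zero).
#'
#' @return A numeric vector of phenotype values, one per row of `inputs`.
#' @examples
#' phenotype(landscape_lp(k = 0), cbind(x = c(1, 2), y = c(2, 0.5)))
#' @export
phenotype <- function(landscape, inputs) {
  UseMethod("phenotype")
}

#' @export
phenotype.ridge_landscape <- function(landscape, inputs) {
  X <- as_input_matrix(inputs, landscape$d)
  if (landscape$type == 2L) {
    if (any(X < 0)) abort("polynomial-ridge inputs must be non-negative")
  } else if (any(X <= 0)) {
    abort("input values must be strictly positive")
  }
  eval_landscape(landscape, X)
}

as_input_matrix <- function(inputs, d) {
  if (is.data.frame(inputs)) inputs <- as.matrix(inputs)
  if (is.null(dim(inputs))) {
    if (length(inputs) != d) {
      abort(sprintf("expected %d input values, got %d", d, length(inputs)))
    }
    inputs <- matrix(inputs, nrow = 1)
  }
  if (ncol(inputs) != d) {
    abort(sprintf("expected %d input columns, got %d", d, ncol(inputs)))
  }
  storage.mode(inputs) <- "double"
  inputs
}

eval_landscape <- function(landscape, X) {
  switch(as.character(landscape$type),
    "0" = {
      x <- X[, 1]; y <- X[, 2]; k <- landscape$k
      if (k == 0) {
        pmin(x, y) # exact limit; avoids cancellation in the discriminant
      } else {
        a <- k + x + y
        0.5 * (a - sqrt(pmax(a^2 - 4 * x * y, 0)))
      }
    },
    "1" = do.call(pmin, as.data.frame(X)),
    "2" = {
      x <- X[, 1]; y <- X[, 2]
      x + y + (x * y)^landscape$n / landscape$xi^(2 * landscape$n - 1)
    },
    "3" = X[, 1] * X[, 2] / (X[, 1] + X[, 2]),
    "4" = (X[, 1] / (1 + X[, 1])) * (X[, 2] / (1 + X[, 2])),
    "5" = interp_phenotype(landscape, log(X[, 1]), log(X[, 2])),
    "98" = { # rotated wrapper
      U <- rotate_log_coords(log(X), -landscape$angle, landscape$center)
      eval_landscape(landscape$base, exp(U))
    },
    "99" = do.call(landscape$fn, unname(as.data.frame(X))),
    abort("unknown landscape type")
  )
}

#' Stabilizing-selection fitness
#'
#' Gaussian stabilizing selection on the log phenotype,
#' \deqn{w(z) = \exp\left(-s \left(\ln \frac{z}{z_{opt}}\right)^2\right),}
#' so that `w(z_opt) = 1`, fitness is symmetric in `log(z/z_opt)`, and the
#' selection factor `s >= 0` sets how quickly fitness decays away from the
#' optimum. Satisfies the power identity `w(z; s') = w(z; s)^(s'/s)`, which is
#' what makes transient selection-shift assessments cheap.
#'
#' @param z Positive phenotype values.
#' @param s Selection factor, `>= 0`.
#' @param z_opt Optimal phenotype value, `> 0`.
#' @return Fitness values in `(0, 1]`.
#' @examples
#' fitness(exp(1), s = 1) # exp(-1)
#' @export
fitness <- function(z, s = 1, z_opt = 1) {
  stopifnot(s >= 0, z_opt > 0)
  if (any(z <= 0)) abort("phenotype values must be strictly positive")
  exp(-s * log(z / z_opt)^2)
}

#' Corner of a ridge landscape
#'
#' The point on the optimal-fitness ridge at which all inputs are balanced
#' (`x = y = ...`), the only region where strong synergistic epistasis can
#' arise. Returns the input values solving `Z(x, x, ...) = z_opt` on the
#' diagonal. For the generalized LP map this is `x = z_opt + sqrt(k z_opt)`
#' (so `x = 1 + sqrt(k)` at `z_opt = 1`).
#'
#' @param landscape A `ridge_landscape`.
#' @param z_opt Optimal phenotype value.
#' @return Numeric vector of length `d`, or an error if the landscape has no
#'   diagonal point at `z_opt` (e.g. lookup or rotated landscapes, which need
#'   explicit start coordinates).
#' @export
corner_inputs <- function(landscape, z_opt = 1) {
  stopifnot(z_opt > 0)
  d <- landscape$d
  x <- switch(as.character(landscape$type),
    "0" = z_opt + sqrt(landscape$k * z_opt),
    "1" = z_opt,
    "3" = 2 * z_opt,
    "4" = {
      if (z_opt >= 1) abort("saturable landscape is bounded above by 1")
      sqrt(z_opt) / (1 - sqrt(z_opt))
    },
    abort(sprintf(
      "no closed-form diagonal corner for %s; supply explicit start inputs",
      class(landscape)[1]
    ))
  )
  rep(x, d)
}

rotate_log_coords <- function(U, angle, center) {
  ca <- cos(angle); sa <- sin(angle)
  u <- U[, 1] - center[1]; v <- U[, 2] - center[2]
  cbind(center[1] + ca * u - sa * v, center[2] + sa * u + ca * v)
}

#' Rotate a two-input landscape
#'
#' Rotates a landscape in the `(ln x, ln y)` plane about a center point
#' (default: the landscape's ridge corner). Rotation by 0 degrees is the
#' identity; rotating by `theta` then `-theta` recovers the base map.
#' Rotation changes the *orientation* of the ridge (the slope of the optimal
#' contour) without changing its curvature, which is how the contribution of
#' ridge orientation to epistasis is isolated.
#'
#' @param base A two-input `ridge_landscape`.
#' @param angle Rotation angle in degrees (counter-clockwise in
#'   `(ln x, ln y)`).
#' @param center Length-2 numeric, the rotation center in `(ln x, ln y)`;
#'   defaults to the log of the corner inputs.
#' @param z_opt Optimal phenotype used to locate the default center.
#' @return A `ridge_landscape` of class `rotated_landscape`.
#' @export
landscape_rotate <- function(base, angle, center = NULL, z_opt = 1) {
  stopifnot(inherits(base, "ridge_landscape"), base$d == 2)
  if (angle == 0) return(base)
  if (is.null(center)) center <- log(corner_inputs(base, z_opt))[1:2]
  new_landscape(
    type = 98L, d = 2L,
    params = list(angle = angle * pi / 180, center = center, base = base),
    class = "rotated_landscape"
  )
}

# Flat representation consumed by the C++ engine.
landscape_cpp_spec <- function(landscape) {
  if (landscape$type == 99L) {
    abort("custom R-function landscapes cannot be used by the compiled engine")
  }
  if (landscape$type == 98L) {
    spec <- landscape_cpp_spec(landscape$base)
    spec$angle <- landscape$angle
    spec$center <- landscape$center
    return(spec)
  }
  spec <- list(type = landscape$type)
  if (landscape$type == 0L) spec$k <- landscape$k
  if (landscape$type == 2L) {
    spec$n <- landscape$n
    spec$xi <- landscape$xi
  }
  if (landscape$type == 5L) {
    spec$table <- landscape$table
    spec$lx0 <- landscape$ln_x[1]
    spec$dlx <- landscape$ln_x[2] - landscape$ln_x[1]
    spec$ly0 <- landscape$ln_y[1]
    spec$dly <- landscape$ln_y[2] - landscape$ln_y[1]
    spec$clamp <- isTRUE(landscape$clamp)
  }
  spec
}
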