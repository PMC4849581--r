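#' Effective fitness under phenotypic noise
#'
#' The effective fitness of a nominal genotype is its fitness averaged over
#' noise realizations: a rotationally symmetric Gaussian kernel (sd =
#' `noise_sd`) applied on log-transformed input values,
#' \deqn{w_e(u, v) = E\left[w(Z(e^{u + U}, e^{v + V}))\right],\quad
#'       U, V \sim N(0, \sigma^2),}
#' computed by tensor-product Gauss-Hermite quadrature (`nodes` points per
#' axis, spanning roughly 5 sd; weights are normalized). Zero noise returns
#' the raw fitness. Noise turns the sharp optimal ridge of small-`k` LP
#' landscapes into a landscape with a peak at the corner, the driver of
#' corner localization.
#'
#' @param landscape A two-input `ridge_landscape`.
#' @param noise_sd Kernel standard deviation (log scale), `>= 0`.
#' @param ln_x,ln_y Grid axes (log input values).
#' @param s,z_opt Stabilizing-selection parameters.
#' @param nodes Gauss-Hermite nodes per axis (>= 21 recommended; convergence
#'   can be checked by doubling).
#' @return A tibble of class `effective_fitness_grid` with columns `ln_x`,
#'   `ln_y`, `w` (raw fitness) and `w_e`.
#' @examples
#' eff <- effective_fitness(landscape_lp(k = 0), 0.2,
#'   ln_x = seq(-0.5, 2, length.out = 41),
#'   ln_y = seq(-0.5, 2, length.out = 41)
#' )
#' @export
effective_fitness <- function(landscape, noise_sd, ln_x, ln_y, s = 1,
                              z_opt = 1, nodes = 21) {
  stopifnot(noise_sd >= 0, landscape$d == 2, nodes >= 3)
  grid <- expand.grid(ln_x = ln_x, ln_y = ln_y)
  u <- grid$ln_x
  v <- grid$ln_y
  w0 <- fitness(eval_landscape(landscape, cbind(exp(u), exp(v))), s, z_opt)
  if (noise_sd == 0) {
    we <- w0
  } else {
    gh <- pracma::gaussHermite(nodes)
    off <- sqrt(2) * noise_sd * gh$x
    wt <- gh$w / sqrt(pi)
    wt <- wt / sum(wt)
    we <- numeric(length(u))
    for (i in seq_len(nodes)) {
      for (j in seq_len(nodes)) {
        zz <- eval_landscape(landscape, cbind(exp(u + off[i]), exp(v + off[j])))
        we <- we + wt[i] * wt[j] * fitness(zz, s, z_opt)
      }
    }
  }
  out <- tibble(ln_x = u, ln_y = v, w = w0, w_e = we)
  structure(out, class = c("effective_fitness_grid", class(out)),
            noise_sd = noise_sd, s = s, z_opt = z_opt,
            landscape = landscape)
}

#' Effective-fitness profile along a ridge arm
#'
#' Projects an effective-fitness grid onto the x-axis: for each `ln_x`
#' column the ridge-top value `max over ln_y of w_e` is taken (so the
#' profile follows the arm even where the optimal contour curves away from
#' the horizontal), indexed by the corner-aligned coordinate
#' `x' = ln x - ln x_corner` and normalized to 1 at the corner. Below noise
#' levels of about 0.1 (for small `k`) the profile is nearly flat; larger
#' noise raises the corner region above the arm plateau, biasing the
#' weak-mutation random walk toward the corner.
#'
#' @param eff An `effective_fitness_grid` from [effective_fitness()].
#' @param corner Length-2 log-coordinates of the corner (default: from the
#'   grid's landscape).
#' @return A tibble with `x_prime`, `w_e` and the normalized `profile`.
#' @export
arm_profile <- function(eff, corner = NULL) {
  stopifnot(inherits(eff, "effective_fitness_grid"))
  if (is.null(corner)) {
    land <- attr(eff, "landscape")
    corner <- log(corner_inputs(land, attr(eff, "z_opt")))[1:2]
  }
  top <- dplyr::summarise(dplyr::group_by(as_tibble(eff), .data$ln_x),
                          w_e = max(.data$w_e), .groups = "drop")
  top <- top[order(top$ln_x), ]
  xp <- top$ln_x - corner[1]
  w0 <- top$w_e[which.min(abs(xp))]
  tibble(x_prime = xp, w_e = top$w_e, profile = top$w_e / w0)
}

#' Weak-mutation random-walk chain along a ridge arm
#'
#' In the origin-fixation regime (`N mu << 1`) the population occupies a
#' single point that jumps along the arm when a mutation fixes. The chain
#' is built on the profile's grid: a proposed move from state `x'` to `x` is
#' drawn from a discretized Gaussian mutation kernel `g(x | x')` (log-scale
#' sd `sigma_mu`), and accepted with the fixation probability of a mutant
#' whose selective advantage is `s_e = ln(w_e(x)/w_e(x'))`. The default
#' fixation form is the diffusion-limit expression
#' `rho = (1 - exp(-2 s_e)) / (1 - exp(-4 N s_e))` (neutral limit
#' `1/(2N)`); a Metropolis-like alternative
#' `rho = min(1, exp(4 N s_e)) / (2N)` is switchable.
#'
#' @param profile Output of [arm_profile()] (columns `x_prime`, `w_e`).
#' @param N Population size.
#' @param sigma_mu Mutation-kernel standard deviation (log scale).
#' @param fixation `"kimura"` (diffusion limit, default) or
#'   `"metropolis"`.
#' @return A `ridge_chain` object: `states`, transition matrix `T`, and the
#'   parameters.
#' @export
build_chain <- function(profile, N, sigma_mu,
                        fixation = c("kimura", "metropolis")) {
  fixation <- match.arg(fixation)
  stopifnot(all(c("x_prime", "w_e") %in% names(profile)), N >= 2,
            sigma_mu > 0)
  x <- sort(profile$x_prime)
  we <- profile$w_e[order(profile$x_prime)]
  m <- length(x)
  if (m < 2) abort("profile needs at least two states")
  # discretized Gaussian proposal, rows normalized
  G <- outer(x, x, function(a, b) exp(-(b - a)^2 / (2 * sigma_mu^2)))
  diag(G) <- 0
  G <- G / rowSums(G)
  if (any(!is.finite(G))) abort("mutation kernel is not normalizable on this grid")
  se <- outer(we, we, function(wi, wj) log(wj / wi))
  rho <- if (fixation == "kimura") {
    r <- (1 - exp(-2 * se)) / (1 - exp(-4 * N * se))
    r[abs(se) < 1e-12] <- 1 / (2 * N)
    r
  } else {
    pmin(1, exp(4 * N * se)) / (2 * N)
  }
  TM <- G * rho
  diag(TM) <- 0
  diag(TM) <- 1 - rowSums(TM)
  if (any(diag(TM) < 0)) abort("invalid transition matrix (negative holding probability)")
  structure(list(states = x, T = TM, N = N, sigma_mu = sigma_mu,
                 fixation = fixation),
            class = "ridge_chain")
}

#' @export
print.ridge_chain <- function(x, ...) {
  cat(sprintf("<ridge_chain> %d states, N = %d, sigma_mu = %g, %s fixation\n",
              length(x$states), x$N, x$sigma_mu, x$fixation))
  invisible(x)
}

#' Stationary law and exceedance probabilities of the walk
#'
#' `stationary_distribution()` returns the left eigenvector of the
#' transition matrix at eigenvalue 1, normalized to a probability vector.
#' `exceedance()` gives `P(distance from corner >= d)`: the tail mass of
#' the stationary law over states at least `d` away from the corner (state
#' distance is `|x'|`). `simulate_chain()` runs the chain itself, for
#' Monte-Carlo cross-checks of the eigen solution.
#'
#' @param chain A `ridge_chain`.
#' @param d Distances at which to evaluate the exceedance.
#' @param distribution A tibble from `stationary_distribution()`.
#' @param n_steps,init Steps and initial state index for
#'   `simulate_chain()`.
#' @return `stationary_distribution()`: tibble with `x_prime` and `prob`;
#'   `exceedance()`: numeric vector, one value per `d`;
#'   `simulate_chain()`: integer vector of visited state indices.
#' @export
stationary_distribution <- function(chain) {
  stopifnot(inherits(chain, "ridge_chain"))
  e <- eigen(t(chain$T))
  i <- which.min(abs(e$values - 1))
  if (abs(e$values[i] - 1) > 1e-8) abort("chain has no unit eigenvalue; is it reducible?")
  v <- abs(Re(e$vectors[, i]))
  tibble(x_prime = chain$states, prob = v / sum(v))
}

#' @rdname stationary_distribution
#' @export
exceedance <- function(distribution, d) {
  stopifnot(all(c("x_prime", "prob") %in% names(distribution)))
  dist0 <- abs(distribution$x_prime)
  vapply(d, function(dd) sum(distribution$prob[dist0 >= dd]), 0)
}

#' @rdname stationary_distribution
#' @export
simulate_chain <- function(chain, n_steps, init = 1L) {
  stopifnot(inherits(chain, "ridge_chain"), n_steps >= 1)
  cum <- t(apply(chain$T, 1, cumsum))
  cpp_chain_sim(cum, as.integer(n_steps), as.integer(init))
}
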