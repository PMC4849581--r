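test_that("generalized LP map matches its closed-form anchor points", {
  lp0 <- landscape_lp(k = 0)
  expect_equal(phenotype(lp0, c(1, 2)), 1)
  # corner identity: z(x, x; k) = 1 at x = 1 + sqrt(k)
  expect_equal(phenotype(landscape_lp(0.25), c(1.5, 1.5)), 1)
  for (k in c(0, 0.01, 0.25, 1)) {
    x <- 1 + sqrt(k)
    expect_equal(phenotype(landscape_lp(k), c(x, x)), 1, tolerance = 1e-12)
    expect_equal(corner_inputs(landscape_lp(k)), rep(x, 2))
  }
  # weak-interaction limit approaches xy/(k+x+y)
  expect_equal(phenotype(landscape_lp(100), c(1, 1)), 0.009805,
               tolerance = 1e-4)
  expect_equal(phenotype(landscape_lp(100), c(1, 1)), 1 / 102,
               tolerance = 2e-4)
})

test_that("LP at k = 0 equals the minimum map to machine precision", {
  set.seed(7)
  X <- matrix(exp(runif(2e4, -2, 2)), ncol = 2)
  z_lp <- phenotype(landscape_lp(0), X)
  z_min <- phenotype(landscape_min(), X)
  expect_lt(max(abs(z_lp - z_min)), 1e-12)
  expect_equal(z_min, pmin(X[, 1], X[, 2]))
})

test_that("LP map is symmetric, continuous in k, and bounded by min + k", {
  set.seed(8)
  X <- matrix(exp(runif(400, -1, 1)), ncol = 2)
  for (k in c(0.01, 0.5, 3)) {
    lp <- landscape_lp(k)
    z <- phenotype(lp, X)
    expect_equal(z, phenotype(lp, X[, 2:1]))
    expect_true(all(z > 0))
    expect_true(all(z <= pmin(X[, 1], X[, 2]) + k + 1e-12))
  }
  expect_error(phenotype(landscape_lp(0.1), c(-1, 2)), "positive")
})

test_that("minimum map handles d inputs and rejects empty input", {
  expect_equal(phenotype(landscape_min(3), c(1, 2, 3)), 1)
  for (d in 2:5) {
    expect_equal(phenotype(landscape_min(d), rep(0.7, d)), 0.7)
  }
  expect_error(landscape_min(1))
  expect_error(landscape_lp(k = 0.5, d = 3), "k = 0")
})

test_that("fitness has its optimum at z_opt, log-symmetry, and monotone decay", {
  expect_equal(fitness(1, s = 5), 1)
  expect_equal(fitness(2.7, s = 0.3, z_opt = 2.7), 1)
  expect_equal(fitness(exp(1), s = 1), exp(-1))
  expect_equal(fitness(2), fitness(0.5))
  a <- seq(1.1, 4, by = 0.2)
  expect_equal(fitness(a * 3, z_opt = 3), fitness(3 / a, z_opt = 3))
  z <- exp(seq(0, 2, by = 0.1))
  expect_true(all(diff(fitness(z)) < 0))
  expect_error(fitness(-1), "positive")
})

test_that("fitness obeys the selection-strength power identity", {
  z <- exp(runif(50, -1, 1))
  expect_equal(fitness(z, s = 5), fitness(z, s = 1)^5)
  expect_equal(fitness(z, s = 1.7), fitness(z, s = 0.5)^(1.7 / 0.5))
})

test_that("polynomial ridge reduces to x + y on the axes and is symmetric", {
  pl <- landscape_poly(n = 2, xi = 0.5)
  expect_equal(phenotype(pl, c(0, 0.3)), 0.3)
  expect_equal(phenotype(pl, c(0.25, 0)), 0.25)
  # x = y = xi, n = 1: (xi^2)/xi = xi, so z = 3 xi
  expect_equal(phenotype(landscape_poly(n = 1, xi = 0.4), c(0.4, 0.4)),
               3 * 0.4)
  set.seed(9)
  X <- matrix(runif(200, 0, 2), ncol = 2)
  expect_equal(phenotype(pl, X), phenotype(pl, X[, 2:1]))
  # strictly increasing in each argument
  expect_true(all(diff(phenotype(pl, cbind(seq(0, 2, 0.1), 1))) > 0))
  expect_error(phenotype(pl, c(-0.1, 1)), "non-negative")
})

test_that("product and saturable maps match their closed forms", {
  expect_equal(phenotype(landscape_product(), c(2, 2)), 1)
  expect_equal(phenotype(landscape_product(), c(1, 3)), 0.75)
  expect_equal(phenotype(landscape_saturable(), c(1e6, 1e6)), 1,
               tolerance = 1e-5)
  set.seed(10)
  X <- matrix(exp(runif(200, -2, 2)), ncol = 2)
  expect_true(all(phenotype(landscape_product(), X) <= pmin(X[, 1], X[, 2])))
  expect_true(all(phenotype(landscape_saturable(), X) < 1))
  expect_error(phenotype(landscape_product(), c(0, 1)), "positive")
})

test_that("rotation is the identity at 0 degrees and invertible", {
  base <- landscape_lp(0.01)
  expect_identical(landscape_rotate(base, 0), base)
  rot <- landscape_rotate(base, 37)
  back <- landscape_rotate(rot, 0) # rotated object kept as-is
  set.seed(11)
  X <- matrix(exp(runif(200, -0.5, 0.5)), ncol = 2)
  # rotating the query forward through the rotated landscape recovers base
  U <- log(X)
  ctr <- rot$center
  Urot <- ridgesim:::rotate_log_coords(U, rot$angle, ctr)
  expect_equal(phenotype(rot, exp(Urot)), phenotype(base, X),
               tolerance = 1e-12)
  # corner is a fixed point of the rotation
  corner <- corner_inputs(base)
  expect_equal(phenotype(rot, corner), phenotype(base, corner))
})

test_that("the C++ engine evaluates landscapes identically to R", {
  set.seed(12)
  X <- matrix(exp(runif(400, -1, 1)), ncol = 2)
  lands <- list(landscape_lp(0), landscape_lp(0.3), landscape_poly(2, 0.5),
                landscape_product(), landscape_saturable(),
                landscape_rotate(landscape_lp(0.01), 45))
  for (land in lands) {
    zr <- ridgesim:::eval_landscape(land, X)
    zc <- ridgesim:::cpp_phenotype_log(ridgesim:::landscape_cpp_spec(land),
                                       log(X))
    expect_equal(zc, zr, tolerance = 1e-12)
  }
})
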