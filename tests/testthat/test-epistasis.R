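test_that("functional epistasis matches hand-computed anchor cases", {
  m <- landscape_min()
  # doubling both inputs from the corner: single mutants unchanged -> h* = 0
  expect_equal(functional_epistasis(m, c(2, 2), c(1, 1)), 0)
  # halving both inputs: each single mutant carries the full effect -> h* = 2
  expect_equal(functional_epistasis(m, c(0.5, 0.5), c(1, 1)), 2)
  # additive landscape: h* = 1 for any pair
  add <- landscape_custom(function(x, y) x + y)
  set.seed(30)
  tgt <- matrix(exp(rnorm(40)), ncol = 2)
  expect_equal(functional_epistasis(add, tgt, c(1, 1)), rep(1, 20))
  # undefined when the full deviation vanishes
  expect_warning(h <- functional_epistasis(m, c(1, 2), c(1, 3)), "undefined")
  expect_true(is.na(h))
})

test_that("functional epistasis generalizes to d loci", {
  m3 <- landscape_min(3)
  # raising all three inputs from a balanced corner: pure synergy
  expect_equal(functional_epistasis(m3, c(2, 2, 2), c(1, 1, 1)), 0)
  # only one input limiting: fully additive
  expect_equal(functional_epistasis(m3, c(5, 5, 2), c(5, 5, 1)), 1)
})

test_that("LP k = 0 and the minimum map give identical epistasis on random pairs", {
  set.seed(31)
  n <- 1000
  tgt <- matrix(exp(runif(2 * n, -1, 1)), ncol = 2)
  ref <- matrix(exp(runif(2 * n, -1, 1)), ncol = 2)
  h_lp <- suppressWarnings(functional_epistasis(landscape_lp(0), tgt, ref))
  h_min <- suppressWarnings(functional_epistasis(landscape_min(), tgt, ref))
  expect_equal(h_lp, h_min, tolerance = 1e-9)
})

test_that("case partition reproduces its hand example and degenerate handling", {
  m <- landscape_min()
  ref <- list(inputs = c(1, 1), z = 1)
  # case at (2, 2) with no developmental noise: H = 1, h = 0, epistasis 1
  p <- partition_case(m, z_case = 2, z_h = 2,
                      heritable_inputs = c(2, 2), control_ref = ref)
  expect_equal(p$H_ind, 1)
  expect_equal(p$h_ind, 0)
  expect_equal(p$epistatic_fraction, 1)
  # z_H at the control phenotype: H = 0
  p2 <- partition_case(m, z_case = 2, z_h = 1,
                       heritable_inputs = c(2, 2), control_ref = ref)
  expect_equal(p2$H_ind, 0)
  # degenerate case flagged and excluded
  p3 <- partition_case(m, z_case = 1, z_h = 1,
                       heritable_inputs = c(1, 2), control_ref = ref)
  expect_true(p3$degenerate)
  expect_true(is.na(p3$H_ind))
})

test_that("with developmental noise off the partition reduces to functional epistasis", {
  land <- landscape_lp(0.05)
  set.seed(32)
  ref <- list(inputs = c(1.3, 1.1), z = phenotype(land, c(1.3, 1.1)))
  tgt <- matrix(exp(runif(60, -0.5, 0.5)), ncol = 2)
  z <- phenotype(land, tgt)
  p <- partition_case(land, z_case = z, z_h = z, heritable_inputs = tgt,
                      control_ref = ref)
  hstar <- functional_epistasis(land, tgt, ref$inputs)
  expect_equal(p$H_ind, rep(1, 30), tolerance = 1e-12)
  expect_equal(p$h_ind, hstar, tolerance = 1e-12)
  expect_equal(p$epistatic_fraction, 1 - hstar, tolerance = 1e-12)
})

test_that("the epistatic fraction is invariant to relabeling loci", {
  land <- landscape_poly(2, 0.5)
  set.seed(33)
  tgt <- matrix(exp(runif(40, -0.5, 0.5)), ncol = 2)
  z <- phenotype(land, tgt)
  ref <- list(inputs = c(0.4, 0.4), z = phenotype(land, c(0.4, 0.4)))
  p1 <- partition_case(land, z, z, tgt, ref)
  p2 <- partition_case(land, z, z, tgt[, 2:1], ref)
  expect_equal(p1$epistatic_fraction, p2$epistatic_fraction)
})

test_that("statistical heritability is 1 on linear landscapes and near 0 for pure noise", {
  set.seed(34)
  dat <- tibble::tibble(x = runif(300, 0.5, 2), y = runif(300, 0.5, 2))
  dat$z <- 2 * dat$x + 0.5 * dat$y + 1
  fit <- statistical_heritability(dat, inputs = c("x", "y"))
  expect_equal(fit$h2, 1)
  dat$z_noise <- rnorm(300)
  fit0 <- statistical_heritability(dat, phenotype = "z_noise",
                                   inputs = c("x", "y"))
  expect_lt(fit0$h2, 0.05)
  expect_error(
    statistical_heritability(tibble::tibble(x = 1:5, y = 1:5, z = rep(1, 5)),
                             inputs = c("x", "y")),
    "variance"
  )
  g <- glance(fit)
  expect_equal(g$h2 + g$statistical_epistasis, 1)
})

test_that("case enrichment at natural prevalence equals the plain estimator", {
  set.seed(35)
  land <- landscape_poly(2, 0.5)
  dat <- tibble::tibble(x = stats::rexp(2000, 5), y = stats::rexp(2000, 5))
  dat$z <- phenotype(land, dat[c("x", "y")])
  plain <- statistical_heritability(dat, inputs = c("x", "y"))
  same <- case_enriched_heritability(dat, inputs = c("x", "y"),
                                     case_fraction = 0.01, enrichment = 0.01)
  expect_equal(same$h2, plain$h2, tolerance = 1e-9)
  # linear landscape stays fully heritable under any enrichment
  dat$z_lin <- dat$x + dat$y
  fit <- case_enriched_heritability(dat, phenotype = "z_lin",
                                    inputs = c("x", "y"), enrichment = 0.5)
  expect_equal(fit$h2, 1)
  expect_error(case_enriched_heritability(dat[0, ], inputs = c("x", "y")),
               "cases|size")
})

test_that("enrichment does not push statistical epistasis above case functional epistasis", {
  # strongly non-linear corner with an exponential population density
  set.seed(36)
  land <- landscape_poly(n = 2, xi = 0.5)
  lambda <- 0.2
  dat <- tibble::tibble(x = stats::rexp(5000, 1 / lambda),
                        y = stats::rexp(5000, 1 / lambda))
  dat$z <- phenotype(land, dat[c("x", "y")])
  enriched <- case_enriched_heritability(dat, inputs = c("x", "y"),
                                         case_fraction = 0.01,
                                         enrichment = 0.5)
  stat_epi <- 1 - enriched$h2
  cases <- dat[rank(-dat$z, ties.method = "first") <= 50, ]
  hstar <- functional_epistasis(land, as.matrix(cases[c("x", "y")]),
                                c(1e-9, 1e-9))
  func_epi <- mean(1 - hstar)
  expect_lt(stat_epi, func_epi)
})
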