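test_that("initial populations sit exactly at the corner with zero variance", {
  tab <- init_population(landscape_lp(0), N = 20)
  expect_true(all(tab$values == 0.5))
  x <- input_values(tab)
  expect_true(all(x == 1))
  tab2 <- init_population(landscape_lp(0.25), N = 20)
  expect_true(all(tab2$values == 0.75))
  z <- phenotype(landscape_lp(0.25), input_values(tab2))
  expect_equal(z, rep(1, 20))
  expect_equal(var(z), 0)
  # rotated landscapes need explicit coordinates
  rot <- landscape_rotate(landscape_lp(0), 30)
  expect_error(init_population(rot, 10), "corner")
  tab3 <- init_population(rot, 10, start_inputs = c(1, 1))
  expect_true(all(input_values(tab3) == 1))
})

test_that("realize_generation applies environment before developmental noise", {
  tab <- init_population(landscape_lp(0), N = 100)
  # no noise: phenotypes from nominal inputs exactly
  g <- realize_generation(tab, landscape_lp(0))
  expect_equal(g$z, rep(1, 100))
  expect_equal(g$w, rep(1, 100))
  # environment only: all phenotypes equal, shifted by delta
  g2 <- realize_generation(tab, landscape_lp(0), delta_env = c(0.2, -0.1))
  expect_equal(unique(g2$xh_1), exp(log(1) + 0.2))
  expect_equal(g2$z, rep(min(exp(0.2), exp(-0.1)), 100))
  expect_equal(g2$z_h, g2$z)
  # developmental noise: z_h stays the environment-only phenotype
  set.seed(5)
  g3 <- realize_generation(tab, landscape_lp(0), sigma_dev = 0.3,
                           delta_env = 0.1)
  expect_equal(g3$z_h, rep(exp(0.1), 100))
  expect_gt(sd(g3$z), 0)
})

test_that("parent sampling is fitness-proportional with distinct pairs", {
  set.seed(6)
  # uniform fitness: counts uniform by chi-squared
  p <- select_parents(rep(1, 20), n_offspring = 5e4)
  counts <- tabulate(p, 20)
  chi <- stats::chisq.test(counts)
  expect_gt(chi$p.value, 0.001)
  expect_true(all(p[, 1] != p[, 2]))
  # fitness (1, 0.5): first individual drawn ~2/3 of the time
  p2 <- select_parents(c(1, 0.5), n_offspring = 3e4)
  expect_equal(mean(p2[, 1] == 1), 2 / 3, tolerance = 0.02)
  expect_error(select_parents(c(0, 0)), "positive fitness")
  expect_error(select_parents(c(1, 0)), "positive fitness")
})

test_that("rejection sampling matches weighted sampling marginals", {
  set.seed(7)
  w <- runif(30)^2
  p <- select_parents(w, n_offspring = 6e4)
  emp <- tabulate(p[, 1], 30) / 6e4
  expect_equal(emp, w / sum(w), tolerance = 0.02)
})

test_that("reproduction copies parental alleles exactly, respecting recombination", {
  set.seed(8)
  N <- 40
  vals <- array(exp(rnorm(N * 3 * 2, 0, 0.5)), dim = c(N, 3, 2))
  lins <- array(seq_len(N * 6), dim = c(N, 3, 2))
  tab <- allele_table(vals, lins)
  parents <- select_parents(rep(1, N))
  # recomb = 0: each transmitted haplotype is one intact parental chromosome
  off0 <- reproduce(tab, parents, recomb = 0)
  for (i in 1:N) {
    for (h in 1:2) {
      p <- parents[i, h]
      match1 <- all(off0$lineage[i, , h] == tab$lineage[p, , 1])
      match2 <- all(off0$lineage[i, , h] == tab$lineage[p, , 2])
      expect_true(match1 || match2)
    }
  }
  # allele values are exact copies (conservation through reproduction)
  off <- reproduce(tab, parents, recomb = 0.5)
  for (l in 1:3) {
    expect_true(all(off$values[, l, ] %in% tab$values[, l, ]))
  }
})

test_that("a heterozygous locus transmits each allele half the time", {
  N <- 2
  vals <- array(c(1, 1, 2, 2), dim = c(1, 2, 2))[rep(1, N), , , drop = FALSE]
  dim(vals) <- c(N, 2, 2)
  lins <- array(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L), dim = c(N, 2, 2))
  tab <- allele_table(vals, lins)
  set.seed(9)
  parents <- matrix(rep(c(1L, 2L), each = 3e4), ncol = 2)
  off <- reproduce(tab, parents, recomb = 0.5)
  frac <- mean(off$lineage[, 1, 1] == 1L)
  expect_equal(frac, 0.5, tolerance = 0.02)
  # free recombination: locus choices independent
  same <- mean((off$lineage[, 1, 1] == 1L) == (off$lineage[, 2, 1] == 1L))
  expect_equal(same, 0.5, tolerance = 0.02)
})

test_that("mutation respects rate, positivity and the allele cap", {
  set.seed(10)
  N <- 2000
  vals <- array(50, dim = c(N, 2, 2))
  tab <- allele_table(vals)
  expect_identical(mutate_alleles(tab, mu = 0, sigma_mu = 1), tab)
  mut <- mutate_alleles(tab, mu = 0.05, sigma_mu = 1, allele_cap = 100)
  changed <- sum(mut$values != tab$values)
  n_slots <- length(vals)
  # accepted mutations are hits minus cap rejections; bound from binomial
  expected_hits <- n_slots * 0.05
  p_reject <- stats::pnorm(log(100 / 50), sd = 1, lower.tail = FALSE)
  expect_lt(abs(changed - expected_hits * (1 - p_reject)),
            3 * sqrt(expected_hits))
  expect_true(all(mut$values > 0))
  expect_true(all(mut$values < 100))
  # mutated alleles get fresh lineage ids
  expect_true(all(mut$lineage[mut$values != tab$values] > 2))
})

test_that("the engine mutates at the configured rate", {
  # mu large enough to count events in a short monomorphic run
  sim <- small_sim(N = 500, generations = 50, burn_in = 0, sample_every = 50,
                   mu = 0.01, sigma_mu = 0.1, sigma_dev = 0, sigma_env = 0,
                   s = 0, seed = 11)
  n_lineages <- sim$final$next_lineage - 3L # founding lineages: 2
  expected <- 2 * 2 * 500 * 0.01 * 50 # 2 chrom x d x N x mu x generations
  expect_lt(abs(n_lineages - expected), 4 * sqrt(expected))
})

test_that("rarest-allele frequencies match brute-force lineage counting", {
  set.seed(12)
  N <- 30
  lins <- array(sample(1:5, N * 2 * 2, replace = TRUE), dim = c(N, 2, 2))
  vals <- array(1, dim = c(N, 2, 2))
  tab <- allele_table(vals, lins)
  got <- rarest_allele_frequency(tab)
  oracle <- vapply(1:N, function(i) {
    f <- c()
    for (l in 1:2) {
      for (h in 1:2) {
        lin <- lins[i, l, h]
        f <- c(f, sum(lins[, l, ] == lin) / (2 * N))
      }
    }
    min(f)
  }, 0)
  expect_equal(got, oracle)
  # monomorphic population: frequency 1
  expect_equal(rarest_allele_frequency(allele_table(vals)), rep(1, N))
  # unique de novo allele in one heterozygote: 1/(2N)
  lins2 <- array(1L, dim = c(N, 2, 2))
  lins2[3, 1, 1] <- 99L
  tab2 <- allele_table(vals, lins2)
  expect_equal(rarest_allele_frequency(tab2, 3), 1 / (2 * N))
})
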