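#' Realize phenotypes and fitness for one generation
#'
#' Applies the full genotype-to-fitness pipeline to a population, in the
#' fixed order: allele sums (nominal inputs) -> environmental shift (shared
#' by all individuals) -> developmental noise (independent per individual
#' and input) -> phenotype -> fitness.
#'
#' @param table An `allele_table`.
#' @param landscape A `ridge_landscape`.
#' @param s,z_opt Stabilizing-selection parameters, see [fitness()].
#' @param sigma_dev Developmental noise level (log-scale sd).
#' @param delta_env Environmental perturbation, length `d` (or scalar,
#'   recycled).
#' @return A tibble with one row per individual: nominal inputs `x_*`,
#'   heritable (environment-adjusted) inputs `xh_*`, effective inputs
#'   `xe_*`, phenotypes `z` (observed) and `z_h` (before developmental
#'   noise), and fitness `w`.
#' @export
realize_generation <- function(table, landscape, s = 1, z_opt = 1,
                               sigma_dev = 0, delta_env = 0) {
  stopifnot(inherits(table, "allele_table"))
  x <- input_values(table)
  d <- ncol(x)
  if (length(delta_env) == 1) delta_env <- rep(delta_env, d)
  xh <- apply_env_shift(x, delta_env)
  xe <- apply_dev_noise(xh, sigma_dev)
  z <- eval_landscape(landscape, xe)
  z_h <- if (sigma_dev == 0) z else eval_landscape(landscape, xh)
  out <- tibble(id = seq_len(nrow(x)))
  for (l in seq_len(d)) out[[paste0("x_", l)]] <- x[, l]
  for (l in seq_len(d)) out[[paste0("xh_", l)]] <- xh[, l]
  for (l in seq_len(d)) out[[paste0("xe_", l)]] <- xe[, l]
  out$z <- z
  out$z_h <- z_h
  out$w <- fitness(z, s, z_opt)
  out
}

#' Draw parents in proportion to fitness
#'
#' Fitness-proportional sampling with replacement by the rejection scheme: a
#' uniformly chosen candidate is accepted if its fitness exceeds a uniform
#' draw on `(0, max fitness)`. Each offspring receives two distinct parents
#' (the second is redrawn on collision); across offspring, parents are drawn
#' with replacement.
#'
#' @param w Numeric vector of fitness values (one per individual).
#' @param n_offspring Number of offspring (default `length(w)`).
#' @return Integer matrix `n_offspring x 2` of parent indices.
#' @export
select_parents <- function(w, n_offspring = length(w)) {
  if (sum(w > 0) < 2) abort("fewer than two individuals with positive fitness")
  N <- length(w)
  wmax <- max(w)
  draw <- function(n) {
    out <- integer(0)
    while (length(out) < n) {
      cand <- sample.int(N, 2 * n, replace = TRUE)
      keep <- w[cand] > runif(2 * n) * wmax
      out <- c(out, cand[keep])
    }
    out[seq_len(n)]
  }
  p1 <- draw(n_offspring)
  p2 <- draw(n_offspring)
  while (any(bad <- p2 == p1)) p2[bad] <- draw(sum(bad))
  cbind(p1, p2, deparse.level = 0)
}

#' Transmit parental chromosomes to offspring
#'
#' For each parent of each offspring, one of the two chromosomes is chosen
#' uniformly at the first locus; between successive loci the copied
#' chromosome is switched with probability `recomb` (0.5 = free
#' recombination, 0 = intact haplotypes). Offspring alleles are exact copies
#' of parental allele values and lineage identifiers.
#'
#' @param table Parent `allele_table`.
#' @param parents Integer matrix `N x 2` from [select_parents()].
#' @param recomb Switch probability between adjacent loci, in `[0, 0.5]`.
#' @return Offspring `allele_table`.
#' @export
reproduce <- function(table, parents, recomb = 0.5) {
  stopifnot(inherits(table, "allele_table"), is.matrix(parents),
            ncol(parents) == 2, recomb >= 0, recomb <= 0.5)
  dm <- dim(table$values)
  d <- dm[2]
  n <- nrow(parents)
  vals <- array(NA_real_, dim = c(n, d, 2))
  lins <- array(NA_integer_, dim = c(n, d, 2))
  for (h in 1:2) {
    p <- parents[, h]
    chrom <- matrix(0L, n, d)
    chrom[, 1] <- sample(0:1, n, replace = TRUE)
    if (d > 1) {
      for (l in 2:d) {
        sw <- runif(n) < recomb
        chrom[, l] <- ifelse(sw, 1L - chrom[, l - 1], chrom[, l - 1])
      }
    }
    for (l in seq_len(d)) {
      idx <- cbind(p, l, chrom[, l] + 1L)
      vals[, l, h] <- table$values[idx]
      lins[, l, h] <- table$lineage[idx]
    }
  }
  allele_table(vals, lins, next_lineage = table$next_lineage)
}

#' Mutate allele values
#'
#' Each allele mutates independently with probability `mu`. A mutation adds
#' a `N(0, sigma_mu^2)` variate to the natural log of the allele value (so
#' values stay positive); proposals exceeding `allele_cap` are rejected and
#' the inherited allele is kept unchanged. Mutated alleles receive fresh
#' lineage identifiers.
#'
#' @param table An `allele_table`.
#' @param mu Mutation probability per allele per generation.
#' @param sigma_mu Log-scale mutational step standard deviation.
#' @param allele_cap Maximum allele value (default 100).
#' @return The mutated `allele_table`.
#' @export
mutate_alleles <- function(table, mu, sigma_mu, allele_cap = 100) {
  stopifnot(inherits(table, "allele_table"), mu >= 0, mu <= 1, sigma_mu >= 0,
            allele_cap > 0)
  if (mu == 0) return(table)
  vals <- table$values
  lins <- table$lineage
  hit <- which(runif(length(vals)) < mu)
  if (length(hit)) {
    prop <- exp(log(vals[hit]) + rnorm(length(hit), 0, sigma_mu))
    ok <- prop < allele_cap
    vals[hit[ok]] <- prop[ok]
    lins[hit[ok]] <- table$next_lineage + seq_len(sum(ok)) - 1L
  }
  allele_table(vals, lins,
               next_lineage = table$next_lineage + length(hit))
}
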