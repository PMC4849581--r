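#' Diploid allele tables
#'
#' The evolving genetic state of a simulated population: for each of `N`
#' individuals, `d` loci and 2 chromosomes, a positive allele value and an
#' integer allele-lineage identifier. An individual's input value at a locus
#' is the sum of its two allele values there. Lineage identifiers let
#' population frequencies of individual alleles be tracked exactly: every
#' founding allele and every new mutation gets a fresh identifier.
#'
#' @param values Numeric array `N x d x 2` of positive allele values.
#' @param lineage Integer array of the same shape (defaults to one lineage
#'   per locus, i.e. a monomorphic founding population).
#' @param next_lineage First identifier available for new mutations.
#' @return An `allele_table` object.
#' @export
allele_table <- function(values, lineage = NULL, next_lineage = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3, dim(values)[3] == 2)
  if (any(values <= 0)) abort("allele values must be strictly positive")
  if (is.null(lineage)) {
    d <- dim(values)[2]
    lineage <- array(rep(seq_len(d), each = dim(values)[1]), dim = dim(values))
  }
  stopifnot(all(dim(lineage) == dim(values)))
  storage.mode(lineage) <- "integer"
  if (is.null(next_lineage)) next_lineage <- max(lineage) + 1L
  structure(list(values = values, lineage = lineage,
                 next_lineage = as.integer(next_lineage)),
            class = "allele_table")
}

#' @export
print.allele_table <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf("<allele_table> N = %d individuals, d = %d loci, %d lineages\n",
              dm[1], dm[2], length(unique(as.vector(x$lineage)))))
  invisible(x)
}

#' Long-format view of an allele table
#'
#' @param x An `allele_table`.
#' @param ... Unused.
#' @return A tibble with one row per allele: `id`, `locus`, `chromosome`,
#'   `value`, `lineage`.
#' @export
as_tibble.allele_table <- function(x, ...) {
  dm <- dim(x$values)
  tibble(
    id = rep(seq_len(dm[1]), times = dm[2] * 2),
    locus = rep(rep(seq_len(dm[2]), each = dm[1]), times = 2),
    chromosome = rep(1:2, each = dm[1] * dm[2]),
    value = as.vector(x$values),
    lineage = as.vector(x$lineage)
  )
}

#' Nominal input values of a population
#'
#' Sums the two allele values at each locus of each individual.
#'
#' @param table An `allele_table`.
#' @return Numeric matrix `N x d` with columns `x_1, ..., x_d`.
#' @export
input_values <- function(table) {
  stopifnot(inherits(table, "allele_table"))
  x <- table$values[, , 1, drop = FALSE] + table$values[, , 2, drop = FALSE]
  dim(x) <- dim(table$values)[1:2]
  colnames(x) <- paste0("x_", seq_len(ncol(x)))
  x
}

#' Initialize a population at the ridge corner
#'
#' Builds the founding population: every individual homozygous at every
#' locus, with allele values chosen so that all inputs are equal and the
#' noise-free phenotype equals `z_opt` (each allele is half the corner input
#' value; e.g. 0.5 for the `k = 0` LP map at `z_opt = 1`, and
#' `(1 + sqrt(k))/2` in general). Landscapes without a diagonal corner
#' (rotated or lookup landscapes) need explicit `start_inputs`.
#'
#' @param landscape A `ridge_landscape`.
#' @param N Population size.
#' @param z_opt Optimal phenotype value.
#' @param start_inputs Optional length-`d` vector of starting input values
#'   overriding the corner solution.
#' @return An `allele_table` with zero phenotypic variance.
#' @export
init_population <- function(landscape, N, z_opt = 1, start_inputs = NULL) {
  stopifnot(N >= 2)
  d <- landscape$d
  x0 <- if (is.null(start_inputs)) corner_inputs(landscape, z_opt) else start_inputs
  stopifnot(length(x0) == d, all(x0 > 0))
  vals <- array(rep(x0 / 2, each = N), dim = c(N, d, 2))
  allele_table(vals)
}

#' Population frequency of each individual's rarest allele
#'
#' For each requested individual, the minimum over its `2d` alleles of that
#' allele lineage's population frequency (lineage count over `2N`, per
#' locus). Severe cases in equilibrium simulations tend to carry at least
#' one rare allele, which is what this statistic quantifies.
#'
#' @param table An `allele_table` with lineage tracking.
#' @param individuals Integer indices (default: everyone).
#' @return Numeric vector of frequencies in `(0, 1]`.
#' @export
rarest_allele_frequency <- function(table, individuals = NULL) {
  stopifnot(inherits(table, "allele_table"))
  if (is.null(table$lineage)) abort("lineage tracking data absent")
  dm <- dim(table$values)
  N <- dm[1]; d <- dm[2]
  if (is.null(individuals)) individuals <- seq_len(N)
  freq <- matrix(NA_real_, N, d)
  for (l in seq_len(d)) {
    lins <- c(table$lineage[, l, 1], table$lineage[, l, 2])
    counts <- table(lins)
    f1 <- as.numeric(counts[as.character(table$lineage[, l, 1])])
    f2 <- as.numeric(counts[as.character(table$lineage[, l, 2])])
    freq[, l] <- pmin(f1, f2) / (2 * N)
  }
  apply(freq[individuals, , drop = FALSE], 1, min)
}
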