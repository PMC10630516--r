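#' Round half away from zero
#'
#' Report-style rounding (0.0005 -> 0.001), as used by the printed tables
#' this package mirrors; base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# deterministic sub-seed derivation so independent simulation stages can be
# reseeded reproducibly from one user-facing seed (kept below 2^31)
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 11 * as.numeric(stream)) %% 2147483647
}

# long genotype tibble -> named list of per-locus call matrices is avoided;
# most computations work directly on the long table. This helper subsets one
# locus with non-missing calls.
locus_calls <- function(g, locus, population = NULL) {
  tab <- tibble::as_tibble(g)
  tab <- tab[tab$locus == locus, ]
  if (!is.null(population)) tab <- tab[tab$population %in% population, ]
  tab
}
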