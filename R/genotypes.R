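#' Diploid codominant genotype tables
#'
#' The central data structure of the package is a long-format tibble with one
#' row per individual x locus combination and columns:
#'
#' * `individual` — accession identifier (character)
#' * `population` — population label (character); each individual belongs to
#'   exactly one population
#' * `locus` — marker name (character)
#' * `allele_1`, `allele_2` — the unordered diploid call as two positive
#'   integer allele identifiers (fragment sizes in base pairs), stored sorted
#'   so that `allele_1 <= allele_2`. A missing genotype has `NA` in both
#'   columns; a half-called genotype is invalid.
#'
#' `as_genotypes()` coerces any data frame with these columns (the allele
#' columns may also be named `allele1`/`allele2`), completes absent
#' individual x locus combinations as missing calls, sorts each call, and
#' validates the result. Locus and individual ordering follow first
#' appearance in the input and are kept in the `"loci"` and `"individuals"`
#' attributes.
#'
#' @param x A data frame with the columns described above.
#' @return A tibble of class `genotypes`.
#' @examples
#' g <- as_genotypes(tibble::tibble(
#'   individual = c("i1", "i1", "i2", "i2"),
#'   population = "P1",
#'   locus      = c("L1", "L2", "L1", "L2"),
#'   allele_1   = c(120L, 95L, 124L, NA),
#'   allele_2   = c(124L, 95L, 124L, NA)
#' ))
#' n_loci(g)
#' @export
as_genotypes <- function(x) {
  if (inherits(x, "genotypes")) {
    return(x)
  }
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  nm <- names(x)
  if ("allele1" %in% nm && !"allele_1" %in% nm) {
    x <- dplyr::rename(x, allele_1 = "allele1", allele_2 = "allele2")
  }
  required <- c("individual", "population", "locus", "allele_1", "allele_2")
  miss <- setdiff(required, names(x))
  if (length(miss) > 0) {
    stop("genotype table is missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  x <- dplyr::mutate(x,
    individual = as.character(.data$individual),
    population = as.character(.data$population),
    locus      = as.character(.data$locus),
    allele_1   = as.integer(.data$allele_1),
    allele_2   = as.integer(.data$allele_2)
  )

  individuals <- unique(x$individual)
  loci <- unique(x$locus)
  pop_map <- dplyr::distinct(x, .data$individual, .data$population)
  if (anyDuplicated(pop_map$individual) > 0) {
    bad <- pop_map$individual[duplicated(pop_map$individual)]
    stop("individual(s) assigned to more than one population: ",
      paste(unique(bad), collapse = ", "),
      call. = FALSE
    )
  }

  dup <- duplicated(x[c("individual", "locus")])
  if (any(dup)) {
    stop(
      "duplicated genotype record(s), e.g. individual '",
      x$individual[dup][1], "' at locus '", x$locus[dup][1], "'",
      call. = FALSE
    )
  }

  # one NA allele with the other present is a half call, not MISSING
  half <- xor(is.na(x$allele_1), is.na(x$allele_2))
  if (any(half)) {
    i <- which(half)[1]
    stop("half-called genotype for individual '", x$individual[i],
      "' at locus '", x$locus[i], "': both alleles or neither must be given",
      call. = FALSE
    )
  }
  bad_id <- !is.na(x$allele_1) & (x$allele_1 <= 0L | x$allele_2 <= 0L)
  if (any(bad_id)) {
    i <- which(bad_id)[1]
    stop("allele identifiers must be positive integers (individual '",
      x$individual[i], "', locus '", x$locus[i], "')",
      call. = FALSE
    )
  }

  # store each unordered pair sorted
  a1 <- pmin(x$allele_1, x$allele_2)
  a2 <- pmax(x$allele_1, x$allele_2)
  x$allele_1 <- a1
  x$allele_2 <- a2

  # complete absent individual x locus combinations as MISSING
  full <- tidyr::expand_grid(individual = individuals, locus = loci)
  x <- dplyr::left_join(full, dplyr::select(x, -"population"),
    by = c("individual", "locus")
  )
  x <- dplyr::left_join(x, pop_map, by = "individual")
  x <- dplyr::select(
    x, "individual", "population", "locus", "allele_1", "allele_2"
  )

  empty <- x |>
    dplyr::summarise(
      any_data = any(!is.na(.data$allele_1)),
      .by = "locus"
    ) |>
    dplyr::filter(!.data$any_data)
  if (nrow(empty) > 0) {
    stop("locus with no genotyped individual: ",
      paste(empty$locus, collapse = ", "),
      call. = FALSE
    )
  }

  structure(x,
    class = c("genotypes", class(tibble::tibble())),
    individuals = individuals,
    loci = loci
  )
}

#' @rdname as_genotypes
#' @export
is_genotypes <- function(x) inherits(x, "genotypes")

#' Accessors for genotype tables
#'
#' @param g A genotype table (anything accepted by [as_genotypes()]).
#' @return `gt_loci()` and `gt_individuals()` return character vectors in
#'   first-appearance order; `gt_populations()` a named character vector
#'   mapping individual to population label; `n_loci()`/`n_individuals()`
#'   counts.
#' @export
gt_loci <- function(g) {
  g <- as_genotypes(g)
  attr(g, "loci")
}

#' @rdname gt_loci
#' @export
gt_individuals <- function(g) {
  g <- as_genotypes(g)
  attr(g, "individuals")
}

#' @rdname gt_loci
#' @export
gt_populations <- function(g) {
  g <- as_genotypes(g)
  map <- dplyr::distinct(tibble::as_tibble(g), .data$individual, .data$population)
  stats::setNames(map$population, map$individual)
}

#' @rdname gt_loci
#' @export
n_loci <- function(g) length(gt_loci(g))

#' @rdname gt_loci
#' @export
n_individuals <- function(g) length(gt_individuals(g))

#' @export
print.genotypes <- function(x, ...) {
  pops <- unique(x$population)
  cat(sprintf(
    "<genotypes> %d individuals x %d loci, %d population%s\n",
    length(attr(x, "individuals")), length(attr(x, "loci")),
    length(pops), if (length(pops) == 1) "" else "s"
  ))
  NextMethod()
}
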