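#' Simulation configuration for synthetic genotype matrices
#'
#' Defaults emulate the study system the package's statistics were built
#' around: 7 natural populations of very unequal size (23, 22, 9, 1, 7,
#' 57, 1 — 120 accessions in total), 19 codominant SSR loci carrying 7-20
#' alleles each, island-model differentiation around Fst 0.2, per-population
#' inbreeding spanning negative and positive values, and about 5% missing
#' genotypes so per-locus sample sizes fall in the observed 95-120 range.
#'
#' @param n_populations Number of populations.
#' @param sizes Integer vector of population sizes (length
#'   `n_populations`).
#' @param n_loci Number of loci.
#' @param allele_range Length-2 integer range of allele counts per locus.
#' @param alpha Dirichlet concentration of the ancestral frequency vector.
#' @param theta Target differentiation (Balding-Nichols Fst), in `[0, 1)`.
#' @param f Within-population inbreeding coefficient(s), recycled to
#'   `n_populations`, each in `(-1, 1)`.
#' @param missing_rate Probability a genotype is masked missing, in
#'   `[0, 1)`.
#' @param seed Mandatory integer seed.
#' @param pop_names Population labels.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 7,
                       sizes = c(23L, 22L, 9L, 1L, 7L, 57L, 1L),
                       n_loci = 19,
                       allele_range = c(7L, 20L),
                       alpha = 1,
                       theta = 0.2,
                       f = c(0.11, 0.12, 0.06, 0, -0.12, 0.29, 0),
                       missing_rate = 0.05,
                       seed,
                       pop_names = NULL) {
  if (missing(seed)) {
    stop("a seed is mandatory for reproducible simulation", call. = FALSE)
  }
  stopifnot(
    n_populations >= 1, length(sizes) == n_populations, all(sizes >= 1),
    n_loci >= 1, length(allele_range) == 2,
    allele_range[1] >= 2, allele_range[2] >= allele_range[1],
    alpha > 0, missing_rate >= 0, missing_rate < 1
  )
  if (theta < 0 || theta >= 1) {
    stop("theta must lie in [0, 1); theta = 1 is degenerate", call. = FALSE)
  }
  f <- rep_len(f, n_populations)
  if (any(f <= -1 | f >= 1)) {
    stop("per-population inbreeding f must lie in (-1, 1)", call. = FALSE)
  }
  if (is.null(pop_names)) {
    pop_names <- paste0("POP", seq_len(n_populations))
  }
  structure(
    list(
      n_populations = as.integer(n_populations),
      sizes = as.integer(sizes), n_loci = as.integer(n_loci),
      allele_range = as.integer(allele_range), alpha = alpha,
      theta = theta, f = f, missing_rate = missing_rate,
      seed = as.integer(seed), pop_names = pop_names
    ),
    class = "sim_config"
  )
}

rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1 # numeric underflow guard
  x / sum(x)
}

#' Simulate ancestral and per-population allele frequencies
#'
#' Balding-Nichols island model: the ancestral frequency vector of each
#' locus is Dirichlet(`alpha`) over its alleles; for `theta > 0` each
#' population draws its own vector from Dirichlet(`p * (1 - theta) /
#' theta`), whose expectation is `p` and whose variance per allele is
#' `theta * p * (1 - p)` — so `theta` is the model's Fst. For `theta = 0`
#' every population carries the ancestral vector exactly.
#'
#' Allele identifiers are plausible fragment sizes: each locus draws a
#' motif length (2-6 bp) and an offset, and alleles step by the motif
#' length.
#'
#' @param config A [sim_config()].
#' @return A list with `ancestral` and `populations` tibbles (`locus`,
#'   `allele`, `freq`, the latter also `population`).
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1))
  loci <- sprintf("L%02d", seq_len(config$n_loci))
  anc <- purrr::map(seq_len(config$n_loci), function(l) {
    k <- sample(seq(config$allele_range[1], config$allele_range[2]), 1)
    motif_len <- sample(2:6, 1)
    offset <- sample(100:250, 1)
    tibble::tibble(
      locus = loci[l],
      allele = as.integer(offset + motif_len * (seq_len(k) - 1)),
      freq = rdirichlet(rep(config$alpha, k))
    )
  })
  ancestral <- dplyr::bind_rows(anc)
  pops <- purrr::map(seq_len(config$n_populations), function(i) {
    per_locus <- purrr::map(anc, function(a) {
      fr <- if (config$theta == 0) {
        a$freq
      } else {
        rdirichlet(a$freq * (1 - config$theta) / config$theta)
      }
      tibble::tibble(
        population = config$pop_names[i], locus = a$locus,
        allele = a$allele, freq = fr
      )
    })
    dplyr::bind_rows(per_locus)
  })
  list(ancestral = ancestral, populations = dplyr::bind_rows(pops))
}

#' Simulate a diploid genotype block from population frequencies
#'
#' Inbreeding-adjusted Hardy-Weinberg sampling: homozygote `ii` has
#' probability `p_i^2 + f * p_i * (1 - p_i)` and heterozygote `ij`
#' (`i < j`) `(1 - f) * 2 * p_i * p_j`; negative `f` raises heterozygosity
#' symmetrically. `f` must keep all genotype probabilities nonnegative
#' (`f >= -min(p) / (1 - min(p))` among segregating alleles), otherwise the
#' call is refused naming the binding constraint. With
#' `clamp_negative = TRUE` the negative homozygote probabilities produced
#' by a negative `f` at rare alleles are instead floored at zero and the
#' genotype distribution renormalized, attenuating the heterozygote excess
#' only for alleles rarer than about `|f| / (1 + |f|)`; this is how
#' [generate_dataset()] accommodates negative inbreeding under continuous
#' Dirichlet frequencies, whose smallest frequencies are arbitrarily close
#' to zero. Calls are then masked missing independently at `missing_rate`.
#'
#' @param freqs Tibble `locus`, `allele`, `freq` for one population.
#' @param size Number of individuals.
#' @param f Inbreeding coefficient.
#' @param missing_rate Missing-genotype probability.
#' @param population Population label.
#' @param ids Optional individual identifiers.
#' @param clamp_negative Floor negative genotype probabilities instead of
#'   refusing an inadmissible negative `f`.
#' @return A tibble of genotype rows (not yet validated).
#' @export
simulate_genotypes <- function(freqs, size, f = 0, missing_rate = 0,
                               population = "POP1", ids = NULL,
                               clamp_negative = FALSE) {
  stopifnot(size >= 1, f > -1, f < 1)
  if (is.null(ids)) ids <- sprintf("%s_%03d", population, seq_len(size))
  out <- purrr::map(split(freqs, freqs$locus), function(fl) {
    p <- fl$freq
    k <- length(p)
    # genotype categories: all unordered pairs (i <= j)
    idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
    prob <- ifelse(
      idx[, 1] == idx[, 2],
      p[idx[, 1]]^2 + f * p[idx[, 1]] * (1 - p[idx[, 1]]),
      (1 - f) * 2 * p[idx[, 1]] * p[idx[, 2]]
    )
    if (any(prob < -1e-12) && !clamp_negative) {
      pmin_seg <- min(p[p > 0])
      stop("inadmissible inbreeding f = ", f, ": homozygote probability ",
        "p^2 + f p (1 - p) < 0; requires f >= ",
        signif(-pmin_seg / (1 - pmin_seg), 3), " at this locus",
        call. = FALSE
      )
    }
    prob <- pmax(prob, 0)
    prob <- prob / sum(prob)
    draw <- sample.int(nrow(idx), size, replace = TRUE, prob = prob)
    tibble::tibble(
      individual = ids,
      population = population,
      locus = fl$locus[1],
      allele_1 = fl$allele[idx[draw, 1]],
      allele_2 = fl$allele[idx[draw, 2]]
    )
  })
  out <- dplyr::bind_rows(out)
  if (missing_rate > 0) {
    mask <- stats::runif(nrow(out)) < missing_rate
    out$allele_1[mask] <- NA_integer_
    out$allele_2[mask] <- NA_integer_
  }
  out
}

#' Generate a full synthetic dataset with known truth
#'
#' Draws frequencies with [simulate_frequencies()] and genotypes for every
#' population with [simulate_genotypes()], each stage reseeded
#' deterministically from the config seed so the result is reproducible
#' byte for byte.
#'
#' @param config A [sim_config()].
#' @return A list with `genotypes` (a validated [genotypes][as_genotypes]
#'   table) and `truth` (the config plus the simulated ancestral and
#'   per-population frequencies).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  freqs <- simulate_frequencies(config)
  blocks <- purrr::map(seq_len(config$n_populations), function(i) {
    set.seed(derive_seed(config$seed, 1000 + i))
    pop <- config$pop_names[i]
    simulate_genotypes(
      freqs$populations[freqs$populations$population == pop,
        c("locus", "allele", "freq")
      ],
      size = config$sizes[i], f = config$f[i],
      missing_rate = config$missing_rate, population = pop,
      clamp_negative = TRUE
    )
  })
  tab <- dplyr::bind_rows(blocks)
  # a locus masked empty in a tiny simulation would be invalid; re-expose
  # one random call per empty locus rather than fail
  empty <- setdiff(unique(tab$locus), tab$locus[!is.na(tab$allele_1)])
  for (l in empty) {
    i <- which(tab$locus == l)[1]
    fl <- freqs$populations[
      freqs$populations$locus == l &
        freqs$populations$population == tab$population[i],
    ]
    a <- fl$allele[which.max(fl$freq)]
    tab$allele_1[i] <- a
    tab$allele_2[i] <- a
  }
  list(
    genotypes = as_genotypes(tab),
    truth = list(
      config = config,
      ancestral = freqs$ancestral,
      populations = freqs$populations
    )
  )
}
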