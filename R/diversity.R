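#' Allele frequencies at a locus
#'
#' Each non-missing diploid call contributes two allele observations; `N` is
#' the number of non-missing individuals in scope.
#'
#' @param g A genotype table.
#' @param locus Locus name.
#' @param scope `NULL` for the whole sample, or one or more population
#'   labels.
#' @return A tibble with columns `locus`, `scope`, `allele`, `freq`, `N`.
#' @export
allele_frequencies <- function(g, locus, scope = NULL) {
  g <- as_genotypes(g)
  if (!locus %in% gt_loci(g)) {
    stop("unknown locus '", locus, "'", call. = FALSE)
  }
  tab <- locus_calls(g, locus, scope)
  tab <- tab[!is.na(tab$allele_1), ]
  if (nrow(tab) == 0) {
    stop("no genotyped individual at locus '", locus, "' in scope '",
      if (is.null(scope)) "all" else paste(scope, collapse = ","), "'",
      call. = FALSE
    )
  }
  alleles <- c(tab$allele_1, tab$allele_2)
  cnt <- table(alleles)
  tibble::tibble(
    locus = locus,
    scope = if (is.null(scope)) "all" else paste(scope, collapse = ","),
    allele = as.integer(names(cnt)),
    freq = as.numeric(cnt) / length(alleles),
    N = nrow(tab)
  )
}

# core statistics from an allele-frequency vector plus the calls they came
# from; p sums to 1
stats_from_freqs <- function(p, ho, n) {
  sum_p2 <- sum(p^2)
  he <- 1 - sum_p2
  pic <- 1 - sum_p2 -
    (sum(outer(p^2, p^2))[1] - sum(p^4)) # = sum_{i<j} 2 p_i^2 p_j^2
  tibble::tibble(
    N = n,
    Na = length(p),
    Ne = 1 / sum_p2,
    I = -sum(ifelse(p > 0, p * log(p), 0)),
    Ho = ho,
    He = he,
    uHe = he * 2 * n / (2 * n - 1),
    F = ifelse(he > 0, 1 - ho / he, NA_real_),
    PIC = pic
  )
}

locus_record <- function(g, locus, scope = NULL) {
  tab <- locus_calls(g, locus, scope)
  tab <- tab[!is.na(tab$allele_1), ]
  if (nrow(tab) == 0) {
    return(NULL)
  }
  alleles <- c(tab$allele_1, tab$allele_2)
  p <- as.numeric(table(alleles)) / length(alleles)
  ho <- mean(tab$allele_1 != tab$allele_2)
  stats_from_freqs(p, ho, nrow(tab))
}

#' Per-locus or per-population diversity statistics
#'
#' For `by = "locus"` one row per locus over the whole sample; for
#' `by = "population"` the per-locus statistics are computed within each
#' population and averaged (unweighted) over loci, with standard errors
#' (sd over loci / sqrt(number of loci)). Both modes append an unweighted
#' `Mean` row over the groups (`NA` cells excluded with the divisor
#' reduced).
#'
#' Columns follow the GenAlEx conventions: `N` genotyped individuals, `Na`
#' observed and `Ne` effective (1/sum p^2) allele numbers, `I` Shannon's
#' information index (natural log), `Ho`/`He`/`uHe` observed, expected and
#' unbiased expected heterozygosity (`uHe = He * 2N/(2N-1)`), `F = 1 -
#' Ho/He` the fixation index (`NA` when `He = 0`), and `PIC` Botstein's
#' polymorphism information content.
#'
#' @param g A genotype table.
#' @param by `"locus"` or `"population"`.
#' @return A tibble; first column `locus` or `population` (last row
#'   `"Mean"`).
#' @export
diversity_table <- function(g, by = c("locus", "population")) {
  g <- as_genotypes(g)
  by <- match.arg(by)
  if (by == "locus") {
    rows <- purrr::map(gt_loci(g), function(l) {
      dplyr::bind_cols(tibble::tibble(locus = l), locus_record(g, l))
    })
    out <- dplyr::bind_rows(rows)
    mean_row <- dplyr::bind_cols(
      tibble::tibble(locus = "Mean"),
      dplyr::summarise(
        out,
        dplyr::across(dplyr::where(is.numeric), ~ mean(.x, na.rm = TRUE))
      )
    )
    return(dplyr::bind_rows(out, mean_row))
  }

  pops <- unique(unname(gt_populations(g)))
  rows <- purrr::map(pops, function(pop) {
    per_locus <- dplyr::bind_rows(
      purrr::map(gt_loci(g), function(l) locus_record(g, l, scope = pop))
    )
    means <- dplyr::summarise(
      per_locus,
      dplyr::across(dplyr::everything(), ~ mean(.x, na.rm = TRUE))
    )
    ses <- dplyr::summarise(
      per_locus,
      dplyr::across(dplyr::everything(),
        ~ stats::sd(.x, na.rm = TRUE) / sqrt(sum(!is.na(.x))),
        .names = "se_{.col}"
      )
    )
    dplyr::bind_cols(
      tibble::tibble(
        population = pop,
        n_samples = sum(unname(gt_populations(g)) == pop)
      ),
      means, ses
    )
  })
  out <- dplyr::bind_rows(rows)
  mean_row <- dplyr::bind_cols(
    tibble::tibble(population = "Mean"),
    dplyr::summarise(
      out,
      dplyr::across(dplyr::where(is.numeric), ~ mean(.x, na.rm = TRUE))
    )
  )
  dplyr::bind_rows(out, mean_row)
}

#' Chi-square test for Hardy-Weinberg equilibrium at a locus
#'
#' Goodness of fit of the observed genotype counts to Hardy-Weinberg
#' expectations computed from the observed allele frequencies; for `g`
#' alleles the degrees of freedom are `g(g-1)/2`.
#'
#' @param g A genotype table.
#' @param locus Locus name; default all loci.
#' @param scope Optional population restriction.
#' @return A tibble with columns `locus`, `statistic`, `df`, `p_value`
#'   (`NA` rows for monomorphic loci).
#' @export
hwe_chi2 <- function(g, locus = NULL, scope = NULL) {
  g <- as_genotypes(g)
  loci <- if (is.null(locus)) gt_loci(g) else locus
  rows <- purrr::map(loci, function(l) {
    tab <- locus_calls(g, l, scope)
    tab <- tab[!is.na(tab$allele_1), ]
    n <- nrow(tab)
    alleles <- sort(unique(c(tab$allele_1, tab$allele_2)))
    k <- length(alleles)
    if (k < 2) {
      return(tibble::tibble(
        locus = l, statistic = NA_real_, df = NA_integer_, p_value = NA_real_
      ))
    }
    p <- as.numeric(table(factor(c(tab$allele_1, tab$allele_2),
      levels = alleles
    ))) / (2 * n)
    # observed and expected counts over all g(g+1)/2 genotype categories
    obs <- exp_ <- matrix(0, k, k)
    for (r in seq_len(n)) {
      i <- match(tab$allele_1[r], alleles)
      j <- match(tab$allele_2[r], alleles)
      obs[i, j] <- obs[i, j] + 1
    }
    for (i in seq_len(k)) {
      for (j in i:k) {
        exp_[i, j] <- if (i == j) n * p[i]^2 else 2 * n * p[i] * p[j]
      }
    }
    idx <- upper.tri(exp_, diag = TRUE)
    stat <- sum((obs[idx] - exp_[idx])^2 / exp_[idx])
    df <- k * (k - 1) / 2
    tibble::tibble(
      locus = l, statistic = stat, df = as.integer(df),
      p_value = stats::pchisq(stat, df, lower.tail = FALSE)
    )
  })
  dplyr::bind_rows(rows)
}

#' Private alleles per population
#'
#' Counts, for each population, the alleles observed in that population and
#' in no other.
#'
#' @param g A genotype table with at least two populations (a single
#'   population triggers a warning: every allele is trivially private).
#' @return A tibble with columns `population`, `n_private`.
#' @export
private_alleles <- function(g) {
  g <- as_genotypes(g)
  tab <- tibble::as_tibble(g)
  tab <- tab[!is.na(tab$allele_1), ]
  long <- tidyr::pivot_longer(tab, c("allele_1", "allele_2"),
    values_to = "allele"
  )
  pops <- unique(unname(gt_populations(g)))
  if (length(pops) < 2) {
    warning("single population: every allele is private by definition")
  }
  seen <- dplyr::distinct(long, .data$population, .data$locus, .data$allele)
  seen <- dplyr::mutate(seen,
    n_pops = dplyr::n_distinct(.data$population),
    .by = c("locus", "allele")
  )
  counts <- seen |>
    dplyr::filter(.data$n_pops == 1) |>
    dplyr::count(.data$population, name = "n_private")
  tibble::tibble(population = pops) |>
    dplyr::left_join(counts, by = "population") |>
    dplyr::mutate(n_private = dplyr::coalesce(.data$n_private, 0L))
}
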