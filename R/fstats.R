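# Per-locus building blocks shared by the F-statistic and Nei-distance
# estimators: unweighted per-population allele frequencies, per-population
# expected/observed heterozygosity, and the total-population heterozygosity
# from the unweighted mean frequency vector.
locus_pop_summary <- function(g, locus, pops) {
  tab <- locus_calls(g, locus, pops)
  tab <- tab[!is.na(tab$allele_1), ]
  present <- intersect(pops, unique(tab$population))
  if (length(present) < 2) {
    return(NULL)
  }
  alleles <- sort(unique(c(tab$allele_1, tab$allele_2)))
  pmat <- sapply(present, function(pop) {
    sub <- tab[tab$population == pop, ]
    as.numeric(table(factor(c(sub$allele_1, sub$allele_2), levels = alleles))) /
      (2 * nrow(sub))
  })
  pmat <- matrix(pmat, nrow = length(alleles), dimnames = list(NULL, present))
  ho <- vapply(present, function(pop) {
    sub <- tab[tab$population == pop, ]
    mean(sub$allele_1 != sub$allele_2)
  }, numeric(1))
  hs_pop <- 1 - colSums(pmat^2)
  pbar <- rowMeans(pmat)
  list(
    pmat = pmat, alleles = alleles, pops = present,
    hs = mean(hs_pop), ht = 1 - sum(pbar^2), ho = mean(ho)
  )
}

#' Wright's F-statistics and gene flow per locus
#'
#' Nei/GenAlEx frequency-based estimators. At each locus, with unweighted
#' (per-population) means: `Hs` is the mean within-population expected
#' heterozygosity, `Ht = 1 - sum(pbar^2)` the total heterozygosity from the
#' unweighted mean allele-frequency vector, and `Ho` the mean observed
#' heterozygosity. Then `Fis = (Hs - Ho)/Hs`, `Fit = (Ht - Ho)/Ht`,
#' `Fst = (Ht - Hs)/Ht`, and the gene flow estimate `Nm` follows from
#' [nm_from_fst()]. The algebraic identity `(1 - Fit) = (1 - Fis)(1 - Fst)`
#' holds exactly for these forms. A final unweighted `Mean` row averages
#' each column over loci.
#'
#' Populations with no data at a locus are dropped from that locus's means;
#' a locus monomorphic over the whole sample yields `NA`s.
#'
#' @param g A genotype table with at least two populations.
#' @return A tibble with columns `locus`, `Fis`, `Fit`, `Fst`, `Nm`.
#' @export
fstats_by_locus <- function(g) {
  g <- as_genotypes(g)
  pops <- unique(unname(gt_populations(g)))
  if (length(pops) < 2) {
    stop("F-statistics require at least two populations", call. = FALSE)
  }
  rows <- purrr::map(gt_loci(g), function(l) {
    s <- locus_pop_summary(g, l, pops)
    if (is.null(s) || s$ht <= 0) {
      return(tibble::tibble(
        locus = l, Fis = NA_real_, Fit = NA_real_, Fst = NA_real_,
        Nm = NA_real_
      ))
    }
    fst <- (s$ht - s$hs) / s$ht
    tibble::tibble(
      locus = l,
      Fis = if (s$hs > 0) (s$hs - s$ho) / s$hs else NA_real_,
      Fit = (s$ht - s$ho) / s$ht,
      Fst = fst,
      Nm = nm_from_fst(fst)
    )
  })
  out <- dplyr::bind_rows(rows)
  mean_row <- dplyr::bind_cols(
    tibble::tibble(locus = "Mean"),
    dplyr::summarise(
      out,
      dplyr::across(dplyr::where(is.numeric), ~ mean(.x, na.rm = TRUE))
    )
  )
  dplyr::bind_rows(out, mean_row)
}

#' Gene flow from a differentiation coefficient
#'
#' Island-model estimate of the effective number of migrants per
#' generation, `Nm = (1 - Fst) / (4 Fst)`. Monotone decreasing in `Fst`;
#' `Fst <= 0` (no differentiation) yields `NA`, `Fst = 1` yields `0`.
#'
#' @param fst Numeric vector of differentiation coefficients in `(0, 1]`.
#' @return Numeric vector of `Nm` values.
#' @examples
#' nm_from_fst(0.2) # 1
#' @export
nm_from_fst <- function(fst) {
  ifelse(is.na(fst) | fst <= 0, NA_real_, (1 - fst) / (4 * fst))
}

#' Pairwise population differentiation and gene flow
#'
#' For every population pair, Fst is computed from the two-population
#' restriction of the per-locus Nei estimators, combining loci by
#' averaging `Hs` and `Ht` before forming the ratio (ratio of averages,
#' the Nei convention), and `Nm` via [nm_from_fst()]. Loci without data in
#' both members of a pair are excluded for that pair.
#'
#' @param g A genotype table with at least two populations.
#' @return A tibble with columns `pop1`, `pop2`, `Fst`, `Nm`, one row per
#'   unordered pair.
#' @seealso [pairwise_matrix()] to reshape into a labeled square matrix.
#' @export
pairwise_fst <- function(g) {
  g <- as_genotypes(g)
  pops <- unique(unname(gt_populations(g)))
  if (length(pops) < 2) {
    stop("pairwise Fst requires at least two populations", call. = FALSE)
  }
  pairs <- utils::combn(pops, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    per_locus <- purrr::map(
      gt_loci(g), function(l) locus_pop_summary(g, l, pr)
    )
    per_locus <- purrr::compact(per_locus)
    if (length(per_locus) == 0) {
      warning("populations ", pr[1], " and ", pr[2],
        " share no locus with data in both; Fst is NA"
      )
      return(tibble::tibble(
        pop1 = pr[1], pop2 = pr[2], Fst = NA_real_, Nm = NA_real_
      ))
    }
    hs <- mean(purrr::map_dbl(per_locus, "hs"))
    ht <- mean(purrr::map_dbl(per_locus, "ht"))
    fst <- if (ht > 0) (ht - hs) / ht else NA_real_
    tibble::tibble(
      pop1 = pr[1], pop2 = pr[2], Fst = fst, Nm = nm_from_fst(fst)
    )
  })
  dplyr::bind_rows(rows)
}

#' Nei's genetic identity and distance between populations
#'
#' Nei (1972) standard identity: per locus `Jxy = sum(px * py)`,
#' `Jx = sum(px^2)`, `Jy = sum(py^2)` over the shared allele support; the
#' three quantities are averaged over loci before the ratio
#' `GI = Jxy_bar / sqrt(Jx_bar * Jy_bar)`, and `GD = -ln(GI)` (reported as
#' `Inf` when `GI = 0`).
#'
#' @param g A genotype table with at least two populations; every pair must
#'   share at least one locus with data in both.
#' @return A tibble with columns `pop1`, `pop2`, `GI`, `GD`.
#' @export
nei_identity_distance <- function(g) {
  g <- as_genotypes(g)
  pops <- unique(unname(gt_populations(g)))
  if (length(pops) < 2) {
    stop("Nei identity requires at least two populations", call. = FALSE)
  }
  pairs <- utils::combn(pops, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    js <- purrr::compact(purrr::map(gt_loci(g), function(l) {
      s <- locus_pop_summary(g, l, pr)
      if (is.null(s)) {
        return(NULL)
      }
      px <- s$pmat[, pr[1]]
      py <- s$pmat[, pr[2]]
      c(jxy = sum(px * py), jx = sum(px^2), jy = sum(py^2))
    }))
    if (length(js) == 0) {
      stop("populations ", pr[1], " and ", pr[2],
        " share no locus with data in both",
        call. = FALSE
      )
    }
    m <- colMeans(do.call(rbind, js))
    gi <- m[["jxy"]] / sqrt(m[["jx"]] * m[["jy"]])
    tibble::tibble(
      pop1 = pr[1], pop2 = pr[2], GI = gi,
      GD = if (gi > 0) -log(gi) else Inf
    )
  })
  dplyr::bind_rows(rows)
}

#' Reshape a pairwise tibble into a labeled square matrix
#'
#' @param pairs Tibble with columns `pop1`, `pop2` and the value column.
#' @param value Name of the value column, e.g. `"Fst"`.
#' @param diag Diagonal fill (0 for distances, 1 for identities).
#' @return Symmetric matrix with population dimnames.
#' @export
pairwise_matrix <- function(pairs, value, diag = 0) {
  pops <- unique(c(pairs$pop1, pairs$pop2))
  m <- matrix(diag, length(pops), length(pops), dimnames = list(pops, pops))
  for (r in seq_len(nrow(pairs))) {
    m[pairs$pop1[r], pairs$pop2[r]] <- pairs[[value]][r]
    m[pairs$pop2[r], pairs$pop1[r]] <- pairs[[value]][r]
  }
  m
}

#' Heatmap of pairwise differentiation and gene flow
#'
#' Tile plot with Fst in the upper triangle and Nm in the lower triangle.
#'
#' @param pairs Output of [pairwise_fst()].
#' @return A ggplot object.
#' @export
plot_pairwise_fst <- function(pairs) {
  pops <- unique(c(pairs$pop1, pairs$pop2))
  upper <- dplyr::transmute(pairs,
    x = .data$pop2, y = .data$pop1, value = .data$Fst, what = "Fst"
  )
  lower <- dplyr::transmute(pairs,
    x = .data$pop1, y = .data$pop2, value = .data$Nm, what = "Nm"
  )
  d <- dplyr::bind_rows(upper, lower)
  d$x <- factor(d$x, levels = pops)
  d$y <- factor(d$y, levels = rev(pops))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.3f", .data$value)),
      size = 3
    ) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = "Pairwise Fst (upper) and Nm (lower)"
    ) +
    ggplot2::theme_minimal()
}
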