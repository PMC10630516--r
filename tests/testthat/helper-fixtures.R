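# fixture builders shared across the suite; everything is generated in code

# quick long-format genotype table: calls is a list of per-locus character
# vectors like c("120/124", "-", "120/120"), one entry per individual
make_genotypes <- function(calls, populations = NULL, loci = NULL) {
  n <- length(calls[[1]])
  if (is.null(loci)) loci <- names(calls)
  if (is.null(loci)) loci <- paste0("L", seq_along(calls))
  if (is.null(populations)) populations <- rep("P1", n)
  rows <- lapply(seq_along(calls), function(l) {
    parts <- strsplit(calls[[l]], "/", fixed = TRUE)
    a1 <- vapply(parts, function(p) {
      if (identical(p, "-")) NA_integer_ else as.integer(p[1])
    }, integer(1))
    a2 <- vapply(parts, function(p) {
      if (identical(p, "-")) NA_integer_ else as.integer(p[2])
    }, integer(1))
    tibble::tibble(
      individual = paste0("i", seq_len(n)),
      population = populations,
      locus = loci[l],
      allele_1 = a1,
      allele_2 = a2
    )
  })
  as_genotypes(dplyr::bind_rows(rows))
}

# independent brute-force SSR scanner: test every start x unit length by
# direct extension, then apply the declared overlap-resolution rule
brute_force_ssrs <- function(s, thresholds = ssr_thresholds()) {
  s <- toupper(s)
  n <- nchar(s)
  period_of <- function(unit) {
    k <- nchar(unit)
    for (p in seq_len(k - 1)) {
      if (k %% p == 0 && unit == strrep(substr(unit, 1, p), k / p)) {
        return(p)
      }
    }
    k
  }
  cand <- list()
  for (u in 1:6) {
    thr <- thresholds[[as.character(u)]]
    for (i in seq_len(max(0, n - u + 1))) {
      unit <- substr(s, i, i + u - 1)
      if (grepl("N", unit) || period_of(unit) < u) next
      k <- 1
      while (i + (k + 1) * u - 1 <= n &&
        substr(s, i + k * u, i + (k + 1) * u - 1) == unit) {
        k <- k + 1
      }
      if (k < thr) next
      cand[[length(cand) + 1]] <- data.frame(
        start = i, end = i + k * u - 1, motif = unit,
        unit_length = u, repeat_count = k
      )
    }
  }
  if (length(cand) == 0) {
    return(data.frame(
      start = integer(), end = integer(), motif = character(),
      unit_length = integer(), repeat_count = integer()
    ))
  }
  tab <- do.call(rbind, cand)
  tab$span <- tab$end - tab$start + 1
  tab <- tab[order(-tab$span, tab$unit_length, tab$start), ]
  kept <- tab[0, ]
  for (i in seq_len(nrow(tab))) {
    if (nrow(kept) == 0 ||
      all(tab$start[i] > kept$end | tab$end[i] < kept$start)) {
      kept <- rbind(kept, tab[i, ])
    }
  }
  kept <- kept[order(kept$start), c(
    "start", "end", "motif", "unit_length", "repeat_count"
  )]
  rownames(kept) <- NULL
  kept
}

random_dna <- function(n, gc = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n,
    replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ), collapse = "")
}

# small random genotype table with some repeated multilocus profiles
random_genotypes <- function(n_ind, n_loci, n_alleles = 3, seed = 1,
                             n_pops = 2) {
  set.seed(seed)
  rows <- list()
  for (l in seq_len(n_loci)) {
    a <- sample(100:140, n_alleles)
    g1 <- sample(a, n_ind, replace = TRUE)
    g2 <- sample(a, n_ind, replace = TRUE)
    rows[[l]] <- tibble::tibble(
      individual = paste0("i", seq_len(n_ind)),
      population = paste0("P", rep_len(seq_len(n_pops), n_ind)),
      locus = paste0("L", l),
      allele_1 = pmin(g1, g2),
      allele_2 = pmax(g1, g2)
    )
  }
  as_genotypes(dplyr::bind_rows(rows))
}
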