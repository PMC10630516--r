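test_that("allele frequencies count two observations per call", {
  g <- make_genotypes(list(L1 = c("100/100", "100/104")))
  fr <- allele_frequencies(g, "L1")
  expect_equal(fr$freq[fr$allele == 100], 0.75)
  expect_equal(fr$freq[fr$allele == 104], 0.25)
  expect_equal(unique(fr$N), 2L)

  g2 <- make_genotypes(list(L1 = c("-", "100/100")))
  fr2 <- allele_frequencies(g2, "L1")
  expect_equal(fr2$freq, 1)
  expect_equal(fr2$N, 1L)

  g3 <- make_genotypes(
    list(L1 = c("100/100", "100/104"), L2 = c("-", "90/90")),
    populations = c("A", "B")
  )
  expect_error(allele_frequencies(g3, "L2", scope = "A"), "no genotyped")
})

test_that("per-locus statistics match closed forms", {
  # p = (0.5, 0.5) via two homozygotes: Ne = 2, He = 0.5, I = ln 2,
  # PIC = 0.375, uHe = He * 4/3, Ho = 0 so F = 1
  g <- make_genotypes(list(L1 = c("100/100", "104/104")))
  d <- diversity_table(g, "locus")
  row <- d[d$locus == "L1", ]
  expect_equal(row$Na, 2)
  expect_equal(row$Ne, 2)
  expect_equal(row$He, 0.5)
  expect_equal(row$I, log(2))
  expect_equal(row$PIC, 0.375)
  expect_equal(row$uHe, 0.5 * 4 / 3)
  expect_equal(row$Ho, 0)
  expect_equal(row$F, 1)

  # monomorphic locus degenerates cleanly with F reported NA
  gm <- make_genotypes(list(
    L1 = c("100/100", "100/100"), L2 = c("90/94", "90/90")
  ))
  dm <- diversity_table(gm, "locus")
  mono <- dm[dm$locus == "L1", ]
  expect_equal(mono$Na, 1)
  expect_equal(mono$Ne, 1)
  expect_equal(mono$He, 0)
  expect_equal(mono$I, 0)
  expect_equal(mono$PIC, 0)
  expect_true(is.na(mono$F))

  # PIC for k equifrequent alleles: k = 4 gives 0.703125
  g4 <- make_genotypes(list(L1 = c("100/104", "108/112")))
  d4 <- diversity_table(g4, "locus")
  expect_equal(d4$PIC[1], 0.703125)
})

test_that("structural identities hold on arbitrary data", {
  g <- random_genotypes(30, 6, n_alleles = 5, seed = 9)
  d <- diversity_table(g, "locus")
  d <- d[d$locus != "Mean", ]
  expect_equal(d$He, 1 - 1 / d$Ne, tolerance = 1e-12)
  expect_equal(d$uHe / d$He, 2 * d$N / (2 * d$N - 1), tolerance = 1e-12)
  expect_equal(d$F, 1 - d$Ho / d$He, tolerance = 1e-12)
  expect_true(all(d$PIC <= d$He + 1e-12))
  expect_true(all(d$Ne <= d$Na))
})

test_that("mean rows average groups unweighted", {
  g <- make_genotypes(list(
    L1 = c("100/104", "100/104", "100/100", "104/104"),
    L2 = c("90/90", "90/94", "90/90", "90/90")
  ))
  d <- diversity_table(g, "locus")
  expect_equal(
    d$He[d$locus == "Mean"],
    mean(d$He[d$locus != "Mean"])
  )
  single <- diversity_table(
    make_genotypes(list(L1 = c("100/104", "100/100"))), "locus"
  )
  expect_equal(
    unlist(single[single$locus == "Mean", -1]),
    unlist(single[single$locus == "L1", -1])
  )
})

test_that("per-population tables report per-locus means and SEs", {
  g <- random_genotypes(24, 5, n_alleles = 4, seed = 3, n_pops = 3)
  dp <- diversity_table(g, "population")
  expect_equal(nrow(dp), 4) # 3 pops + mean row
  expect_true(all(c("n_samples", "se_He", "se_Ne") %in% names(dp)))
  # check one cell against a direct per-locus computation
  pop <- dp$population[1]
  per_locus_he <- vapply(gt_loci(g), function(l) {
    sub <- g[g$locus == l & g$population == pop & !is.na(g$allele_1), ]
    p <- as.numeric(table(c(sub$allele_1, sub$allele_2)))
    p <- p / sum(p)
    1 - sum(p^2)
  }, numeric(1))
  expect_equal(dp$He[1], mean(per_locus_he))
  expect_equal(
    dp$se_He[1], stats::sd(per_locus_he) / sqrt(length(per_locus_he))
  )
})

test_that("HWE chi-square matches hand-computed genotype counts", {
  # exact HW proportions: statistic 0, p = 1
  g_hw <- make_genotypes(list(L1 = c(
    rep("100/100", 25), rep("100/104", 50), rep("104/104", 25)
  )))
  h <- hwe_chi2(g_hw, "L1")
  expect_equal(h$statistic, 0)
  expect_equal(h$p_value, 1)
  expect_equal(h$df, 1L)

  # 50 AA + 50 BB with p = q = 0.5: E = (25, 50, 25), chi2 = 100
  g_fix <- make_genotypes(list(L1 = c(
    rep("100/100", 50), rep("104/104", 50)
  )))
  h2 <- hwe_chi2(g_fix, "L1")
  expect_equal(h2$statistic, 100)
  expect_equal(h2$df, 1L)

  # monomorphic -> NA
  g_mono <- make_genotypes(list(
    L1 = rep("100/100", 4), L2 = c("90/94", rep("90/90", 3))
  ))
  expect_true(is.na(hwe_chi2(g_mono, "L1")$statistic))

  # df = g(g-1)/2
  g3 <- make_genotypes(list(L1 = c("100/104", "104/108", "100/108")))
  expect_equal(hwe_chi2(g3, "L1")$df, 3L)
})

test_that("private alleles equal the brute-force set difference", {
  g <- make_genotypes(
    list(L1 = c("100/104", "104/108")),
    populations = c("A", "B")
  )
  pa <- private_alleles(g)
  expect_equal(pa$n_private[pa$population == "A"], 1L)
  expect_equal(pa$n_private[pa$population == "B"], 1L)

  ident <- make_genotypes(
    list(L1 = c("100/104", "100/104")),
    populations = c("A", "B")
  )
  expect_true(all(private_alleles(ident)$n_private == 0))

  g3 <- random_genotypes(18, 4, n_alleles = 6, seed = 12, n_pops = 3)
  pa3 <- private_alleles(g3)
  tab <- tibble::as_tibble(g3)
  tab <- tab[!is.na(tab$allele_1), ]
  for (pop in unique(tab$population)) {
    n_priv <- 0L
    for (l in gt_loci(g3)) {
      mine <- unique(unlist(tab[
        tab$population == pop & tab$locus == l, c("allele_1", "allele_2")
      ]))
      theirs <- unique(unlist(tab[
        tab$population != pop & tab$locus == l, c("allele_1", "allele_2")
      ]))
      n_priv <- n_priv + length(setdiff(mine, theirs))
    }
    expect_equal(pa3$n_private[pa3$population == pop], n_priv)
  }

  expect_warning(
    private_alleles(make_genotypes(list(L1 = c("100/100", "100/104")))),
    "single population"
  )
})
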