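test_that("config validation enforces the model's domain", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(theta = 1, seed = 1), "degenerate")
  expect_error(sim_config(theta = -0.1, seed = 1), "theta")
  expect_error(sim_config(f = 1.2, seed = 1), "inbreeding")
  expect_error(sim_config(sizes = c(1, 2), seed = 1)) # wrong sizes length
  cfg <- sim_config(seed = 5)
  expect_equal(sum(cfg$sizes), 120L)
  expect_equal(cfg$n_loci, 19L)
})

test_that("theta = 0 copies ancestral frequencies; all vectors normalize", {
  cfg <- sim_config(
    n_populations = 3, sizes = c(4, 4, 4), n_loci = 6,
    theta = 0, f = 0, missing_rate = 0, seed = 9
  )
  fr <- simulate_frequencies(cfg)
  sums <- fr$populations |>
    dplyr::summarise(s = sum(freq), .by = c(population, locus))
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-12)
  merged <- dplyr::left_join(
    fr$populations, fr$ancestral,
    by = c("locus", "allele"), suffix = c("_pop", "_anc")
  )
  expect_equal(merged$freq_pop, merged$freq_anc, tolerance = 1e-12)
})

test_that("small theta concentrates population frequencies near ancestral", {
  cfg <- sim_config(
    n_populations = 5, sizes = rep(2, 5), n_loci = 40,
    allele_range = c(5, 5), theta = 1e-6, f = 0, missing_rate = 0, seed = 13
  )
  fr <- simulate_frequencies(cfg)
  merged <- dplyr::left_join(
    fr$populations, fr$ancestral,
    by = c("locus", "allele"), suffix = c("_pop", "_anc")
  )
  expect_lt(max(abs(merged$freq_pop - merged$freq_anc)), 0.01)
})

test_that("inbreeding-adjusted genotype sampling matches expectations", {
  freqs <- tibble::tibble(
    locus = "L1", allele = c(100L, 104L), freq = c(0.5, 0.5)
  )
  set.seed(1)
  blk <- simulate_genotypes(freqs, size = 10000, f = 0)
  ho <- mean(blk$allele_1 != blk$allele_2)
  expect_equal(ho, 0.5, tolerance = 0.02)

  set.seed(2)
  # f -> 1 gives no heterozygotes (sampled at the admissible boundary)
  blk1 <- simulate_genotypes(freqs, size = 2000, f = 0.999999)
  expect_lt(mean(blk1$allele_1 != blk1$allele_2), 0.001)

  # negative f raises heterozygosity
  set.seed(3)
  blkn <- simulate_genotypes(freqs, size = 10000, f = -0.5)
  expect_equal(
    mean(blkn$allele_1 != blkn$allele_2), 0.75,
    tolerance = 0.02
  )

  # inadmissible negative f refused naming the constraint, unless clamped
  rare <- tibble::tibble(
    locus = "L1", allele = c(100L, 104L), freq = c(0.95, 0.05)
  )
  expect_error(
    simulate_genotypes(rare, size = 10, f = -0.5), "inadmissible"
  )
  expect_silent({
    set.seed(4)
    simulate_genotypes(rare, size = 10, f = -0.5, clamp_negative = TRUE)
  })

  # missing masking at the configured rate
  set.seed(5)
  blkm <- simulate_genotypes(freqs, size = 10000, f = 0, missing_rate = 0.1)
  expect_equal(mean(is.na(blkm$allele_1)), 0.1, tolerance = 0.01)
})

test_that("study-emulating dataset has the right shape and is reproducible", {
  cfg <- sim_config(seed = 77)
  ds <- generate_dataset(cfg)
  expect_equal(n_individuals(ds$genotypes), 120)
  expect_equal(n_loci(ds$genotypes), 19)
  expect_equal(
    as.vector(table(gt_populations(ds$genotypes))[cfg$pop_names]),
    cfg$sizes
  )
  # per-locus genotyped counts mostly inside the emulated 95-120 window
  div <- diversity_table(ds$genotypes, "locus")
  n_per_locus <- div$N[div$locus != "Mean"]
  expect_gte(mean(n_per_locus >= 95 & n_per_locus <= 120), 0.9)

  # determinism: same seed, byte-identical serialization
  ds2 <- generate_dataset(cfg)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(ds$genotypes, p1, "long-csv")
  write_genotypes(ds2$genotypes, p2, "long-csv")
  expect_identical(readLines(p1), readLines(p2))

  # different seed, different data
  ds3 <- generate_dataset(sim_config(seed = 78))
  expect_false(identical(
    tibble::as_tibble(ds$genotypes), tibble::as_tibble(ds3$genotypes)
  ))
})

test_that("simulated data recovers He and within-population F", {
  # truth-based He check: estimated mean He close to the He implied by the
  # simulated population frequencies
  cfg <- sim_config(
    n_populations = 1, sizes = 200L, n_loci = 12, theta = 0,
    f = 0, missing_rate = 0, seed = 101, pop_names = "P1"
  )
  ds <- generate_dataset(cfg)
  true_he <- ds$truth$populations |>
    dplyr::summarise(he = 1 - sum(freq^2), .by = locus)
  div <- diversity_table(ds$genotypes, "locus")
  est_he <- div$He[div$locus != "Mean"]
  se <- stats::sd(est_he - true_he$he) / sqrt(length(est_he))
  expect_lt(abs(mean(est_he - true_he$he)), 2 * se + 0.01)

  # with f = 0 the per-population fixation index stays near zero
  cfgf <- sim_config(
    n_populations = 7, sizes = rep(30L, 7), n_loci = 19, theta = 0.15,
    f = 0, missing_rate = 0, seed = 55, pop_names = paste0("P", 1:7)
  )
  dp <- diversity_table(generate_dataset(cfgf)$genotypes, "population")
  f_mean <- mean(dp$F[dp$population != "Mean"])
  expect_gte(f_mean, -0.05)
  expect_lte(f_mean, 0.05)

  # theta = 0 datasets show essentially no differentiation
  cfg0 <- sim_config(
    n_populations = 2, sizes = c(50L, 50L), n_loci = 19, theta = 0,
    f = 0, missing_rate = 0, seed = 7, pop_names = c("A", "B")
  )
  pw <- pairwise_fst(generate_dataset(cfg0)$genotypes)
  expect_lt(pw$Fst, 0.02)
})
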