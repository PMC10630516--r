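test_that("perfect repeats are found with correct span, motif and class", {
  r <- find_perfect_ssrs(paste0("GATC", strrep("A", 10), "GC"))
  expect_equal(nrow(r), 1)
  expect_equal(r$motif, "A")
  expect_equal(r$repeat_count, 10L)
  expect_equal(r$start, 5L)
  expect_equal(r$end, 14L)
  expect_equal(r$canonical_class, "A/T")

  # below the dinucleotide threshold of 6
  expect_equal(nrow(find_perfect_ssrs("ACACACACAC")), 0)

  r2 <- find_perfect_ssrs("AGAGAGAGAGAG")
  expect_equal(r2$motif, "AG")
  expect_equal(r2$repeat_count, 6L)
  expect_equal(r2$canonical_class, "AG/CT")

  # span identity for perfect repeats
  expect_equal(r2$end - r2$start + 1L, r2$unit_length * r2$repeat_count)
})

test_that("runs break at N, invalid characters error, periodic units reduce", {
  r <- find_perfect_ssrs(paste0(strrep("A", 12), "N", strrep("A", 12)))
  expect_equal(nrow(r), 2)
  expect_error(find_perfect_ssrs("ACGTX"), "invalid nucleotide")
  expect_equal(nrow(find_perfect_ssrs("")), 0)
  # (ATAT) x 5 is reported as (AT) x 10, the smallest period
  r2 <- find_perfect_ssrs(strrep("ATAT", 5))
  expect_equal(r2$motif, "AT")
  expect_equal(r2$repeat_count, 10L)
})

test_that("canonical motif classes collapse rotation and reverse complement", {
  expect_equal(canonical_motif("GA"), "AG/CT")
  expect_equal(canonical_motif("TC"), "AG/CT")
  expect_equal(canonical_motif("TA"), "AT/AT")
  expect_equal(canonical_motif("T"), "A/T")
  expect_equal(canonical_motif("GAA"), "AAG/CTT")
  expect_error(canonical_motif("ATAT"), "periodic")
  expect_error(canonical_motif("ABC"), "1-6 bp")
})

test_that("mining the reverse complement preserves classes and counts", {
  for (seed in 1:3) {
    s <- random_dna(1500, gc = 0.25, seed = seed)
    s <- paste0(s, strrep("AG", 8), random_dna(50), strrep("TTC", 6))
    fwd <- find_perfect_ssrs(s)
    rc <- chartr(
      "ACGT", "TGCA",
      paste(rev(strsplit(s, "")[[1]]), collapse = "")
    )
    rev_ <- find_perfect_ssrs(rc)
    expect_equal(
      sort(paste(fwd$canonical_class, fwd$repeat_count)),
      sort(paste(rev_$canonical_class, rev_$repeat_count))
    )
  }
})

test_that("scanner matches a brute-force oracle on random sequences", {
  for (seed in 1:6) {
    s <- random_dna(2000, gc = 0.2, seed = seed)
    # enrich with planted repeats so matches are non-trivial
    set.seed(seed + 100)
    for (unit in c("A", "AT", "CTT", "AAAG")) {
      pos <- sample(1900, 1)
      reps <- sample(5:12, 1)
      s <- paste0(
        substr(s, 1, pos), strrep(unit, reps),
        substr(s, pos + 1, nchar(s))
      )
    }
    got <- find_perfect_ssrs(s)
    want <- brute_force_ssrs(s)
    expect_equal(
      as.data.frame(got[c(
        "start", "end", "motif", "unit_length", "repeat_count"
      )]),
      want,
      info = paste("seed", seed)
    )
    # no two reported repeats overlap
    if (nrow(got) > 1) {
      expect_true(all(got$start[-1] > got$end[-nrow(got)]))
    }
  }
})

test_that("compound merging fuses repeats within the interruption limit", {
  two <- tibble::tibble(
    seq_id = "s", start = c(10L, 30L), end = c(25L, 45L),
    motif = c("AG", "TTC"), unit_length = c(2L, 3L),
    repeat_count = c(8L, 5L), kind = "perfect",
    canonical_class = c("AG/CT", "AAG/CTT")
  )
  fused <- merge_compound(two, max_interruption = 100)
  expect_equal(nrow(fused), 1)
  expect_equal(fused$kind, "compound")
  expect_equal(fused$start, 10L)
  expect_equal(fused$end, 45L)
  expect_equal(fused$motif, "AG+TTC")
  expect_equal(fused$n_members, 2L)

  far <- two
  far$start[2] <- 180L
  far$end[2] <- 195L
  kept <- merge_compound(far, max_interruption = 100)
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$kind == "perfect"))

  one <- merge_compound(two[1, ], max_interruption = 100)
  expect_equal(one$kind, "perfect")
  expect_equal(one$motif, "AG")
  # member counts partition the input loci
  expect_equal(sum(fused$n_members), nrow(two))
})

test_that("FASTA mining handles wrapped multi-record files", {
  path <- withr::local_tempfile(fileext = ".fa")
  seq1 <- paste0(random_dna(80, seed = 5), strrep("AG", 7), random_dna(40))
  writeLines(c(
    ">unigene1 some description",
    substring(seq1, seq(1, nchar(seq1), 60), pmin(seq(60, nchar(seq1) + 59, 60), nchar(seq1))),
    ">unigene2",
    strrep("TTA", 6)
  ), path)
  r <- mine_ssrs(path)
  expect_setequal(unique(r$seq_id), c("unigene1", "unigene2"))
  expect_true(any(r$canonical_class == "AG/CT"))
})

test_that("summary tables partition loci and percentages close", {
  recs <- dplyr::bind_rows(
    find_perfect_ssrs(paste0("GATC", strrep("A", 10), "GC")),
    find_perfect_ssrs("AGAGAGAGAGAG", seq_id = "s2"),
    tibble::tibble(
      seq_id = "s3", start = 1L, end = 40L, motif = "AG+A",
      unit_length = NA_integer_, repeat_count = NA_integer_,
      kind = "compound", canonical_class = NA_character_
    )
  )
  sm <- summarize_ssrs(recs)
  by_type <- sm$by_type
  expect_equal(by_type$n[by_type$type == "mono"], 1L)
  expect_equal(by_type$n[by_type$type == "di"], 1L)
  expect_equal(by_type$n[by_type$type == "compound"], 1L)
  # compound-inclusive denominator
  expect_equal(sum(by_type$n), 3L)
  expect_equal(sum(by_type$pct), 100, tolerance = 0.02)
  # repeat histogram over perfect loci only, >=10 bin
  expect_equal(sm$repeat_hist$n[sm$repeat_hist$repeats == ">=10"], 1L)
  expect_equal(sm$repeat_hist$n[sm$repeat_hist$repeats == "6"], 1L)

  empty <- summarize_ssrs(find_perfect_ssrs(""))
  expect_true(all(empty$by_type$n == 0))
  # percentage formatting at 2 dp mirrors reported style (6228 of 10681)
  expect_equal(round_half_up(100 * 6228 / 10681, 2), 58.31)
})
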