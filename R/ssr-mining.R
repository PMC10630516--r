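#' Default minimum repeat counts for SSR detection
#'
#' MISA-style thresholds: mononucleotide runs must repeat at least 10 times,
#' dinucleotides 6, tri- to hexanucleotides 5.
#'
#' @return Named integer vector indexed by unit length `"1"`..`"6"`.
#' @export
ssr_thresholds <- function() {
  c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)
}

smallest_period <- function(unit) {
  n <- nchar(unit)
  for (p in seq_len(n - 1)) {
    if (n %% p == 0 &&
      unit == strrep(substr(unit, 1, p), n / p)) {
      return(p)
    }
  }
  n
}

#' Detect perfect SSRs in one nucleotide sequence
#'
#' Scans the forward strand for maximal, non-extendable perfect tandem
#' repeats of unit length 1-6 meeting the per-unit-length minimum repeat
#' count. Repeat units that are themselves periodic (e.g. `ATAT`) are
#' reported at their smallest period; runs are broken at `N`. When candidate
#' repeats of different unit lengths overlap, the longer span wins, ties go
#' to the smaller unit length, then to the leftmost start.
#'
#' @param sequence A single nucleotide string over `A,C,G,T,N`
#'   (case-insensitive).
#' @param thresholds Named vector of minimum repeat counts per unit length,
#'   as returned by [ssr_thresholds()].
#' @param seq_id Identifier recorded in the output.
#' @return A tibble with columns `seq_id`, `start`, `end` (1-based,
#'   inclusive), `motif`, `unit_length`, `repeat_count`, `kind` (`"perfect"`)
#'   and `canonical_class`, ordered by `start`.
#' @export
find_perfect_ssrs <- function(sequence, thresholds = ssr_thresholds(),
                              seq_id = "seq") {
  stopifnot(length(sequence) == 1)
  s <- toupper(as.character(sequence))
  if (nchar(s) == 0) {
    return(empty_ssr_tbl())
  }
  if (grepl("[^ACGTN]", s)) {
    bad <- regmatches(s, regexpr("[^ACGTN]", s))
    stop("invalid nucleotide character '", bad, "' in sequence '", seq_id,
      "'",
      call. = FALSE
    )
  }
  if (any(thresholds < 1)) {
    stop("thresholds must be positive", call. = FALSE)
  }

  cand <- list()
  for (u in 1:6) {
    thr <- thresholds[[as.character(u)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, thr - 1L)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      unit <- substr(s, starts[i], starts[i] + u - 1L)
      if (smallest_period(unit) < u) next # found at its true period instead
      reps <- lens[i] %/% u
      cand[[length(cand) + 1L]] <- list(
        start = starts[i], end = starts[i] + u * reps - 1L,
        motif = unit, unit_length = u, repeat_count = reps
      )
    }
  }
  if (length(cand) == 0) {
    return(empty_ssr_tbl())
  }
  tab <- dplyr::bind_rows(lapply(cand, tibble::as_tibble))
  tab$span <- tab$end - tab$start + 1L
  tab <- tab[order(-tab$span, tab$unit_length, tab$start), ]

  keep <- logical(nrow(tab))
  occ_start <- integer(0)
  occ_end <- integer(0)
  for (i in seq_len(nrow(tab))) {
    if (all(tab$start[i] > occ_end | tab$end[i] < occ_start)) {
      keep[i] <- TRUE
      occ_start <- c(occ_start, tab$start[i])
      occ_end <- c(occ_end, tab$end[i])
    }
  }
  tab <- tab[keep, ]
  tab <- tab[order(tab$start), ]
  tibble::tibble(
    seq_id = seq_id,
    start = tab$start,
    end = tab$end,
    motif = tab$motif,
    unit_length = tab$unit_length,
    repeat_count = tab$repeat_count,
    kind = "perfect",
    canonical_class = unname(vapply(tab$motif, canonical_motif, character(1)))
  )
}

empty_ssr_tbl <- function() {
  tibble::tibble(
    seq_id = character(), start = integer(), end = integer(),
    motif = character(), unit_length = integer(), repeat_count = integer(),
    kind = character(), canonical_class = character()
  )
}

#' Canonical motif class of an SSR repeat unit
#'
#' Standardizes a repeat unit so that all rotations of a motif and of its
#' reverse complement share one label. The label is `"X/Y"` where `X` is the
#' lexicographically smaller of (a) the smallest rotation of the motif and
#' (b) the smallest rotation of its reverse complement, and `Y` is the other;
#' palindromic classes render as self-pairs such as `"AT/AT"`.
#'
#' @param motif Repeat unit of length 1-6; must be aperiodic (reported at
#'   its smallest period).
#' @return Character scalar, e.g. `canonical_motif("GA")` is `"AG/CT"`.
#' @export
canonical_motif <- function(motif) {
  m <- toupper(motif)
  n <- nchar(m)
  if (n < 1 || n > 6 || grepl("[^ACGT]", m)) {
    stop("motif must be a 1-6 bp string over ACGT", call. = FALSE)
  }
  if (smallest_period(m) < n) {
    stop("motif '", m, "' is periodic; reduce it to its smallest period first",
      call. = FALSE
    )
  }
  rot_min <- function(x) {
    k <- nchar(x)
    rots <- vapply(seq_len(k), function(i) {
      paste0(substr(x, i, k), substr(x, 1, i - 1))
    }, character(1))
    min(rots)
  }
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(m, "")[[1]]), collapse = ""))
  a <- rot_min(m)
  b <- rot_min(rc)
  paste0(min(a, b), "/", max(a, b))
}

#' Fuse nearby SSRs into compound loci
#'
#' Consecutive SSRs on the same sequence separated by at most
#' `max_interruption` bases are fused into a single compound record spanning
#' all members (motif strings joined with `"+"`); isolated SSRs pass through
#' unchanged. The output partitions the input loci.
#'
#' @param records SSR tibble as returned by [find_perfect_ssrs()], sorted by
#'   sequence and start.
#' @param max_interruption Maximum gap in bases between fused members
#'   (MISA-style default 100).
#' @return SSR tibble in which fused rows have `kind = "compound"`,
#'   `unit_length` and `repeat_count` `NA`, and `n_members` gives the member
#'   count of every record.
#' @export
merge_compound <- function(records, max_interruption = 100) {
  if (nrow(records) == 0) {
    return(dplyr::mutate(records, n_members = integer()))
  }
  records <- dplyr::arrange(records, .data$seq_id, .data$start)
  gap_prev <- c(
    Inf,
    ifelse(records$seq_id[-1] == records$seq_id[-nrow(records)],
      records$start[-1] - records$end[-nrow(records)] - 1L, Inf
    )
  )
  grp <- cumsum(gap_prev > max_interruption)
  records |>
    dplyr::mutate(.grp = grp) |>
    dplyr::summarise(
      seq_id = .data$seq_id[1],
      start = min(.data$start),
      end = max(.data$end),
      motif = paste(.data$motif, collapse = "+"),
      unit_length = if (dplyr::n() == 1) .data$unit_length[1] else NA_integer_,
      repeat_count = if (dplyr::n() == 1) .data$repeat_count[1] else NA_integer_,
      kind = if (dplyr::n() == 1) .data$kind[1] else "compound",
      canonical_class = if (dplyr::n() == 1) {
        .data$canonical_class[1]
      } else {
        NA_character_
      },
      n_members = dplyr::n(),
      .by = ".grp"
    ) |>
    dplyr::select(-".grp")
}

#' Mine SSRs from a FASTA file
#'
#' Runs [find_perfect_ssrs()] on every record of a (possibly wrapped,
#' multi-record) FASTA file and fuses nearby repeats into compound loci with
#' [merge_compound()].
#'
#' @param fasta Path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @param thresholds Per-unit-length minimum repeat counts.
#' @param max_interruption Compound fusion gap in bases; `NULL` disables
#'   compound detection.
#' @return SSR tibble across all sequences.
#' @export
mine_ssrs <- function(fasta, thresholds = ssr_thresholds(),
                      max_interruption = 100) {
  seqs <- if (inherits(fasta, "DNAStringSet")) {
    fasta
  } else {
    Biostrings::readDNAStringSet(fasta)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  recs <- purrr::map2(
    as.character(seqs), ids,
    function(s, id) find_perfect_ssrs(s, thresholds, seq_id = id)
  )
  out <- dplyr::bind_rows(recs)
  if (!is.null(max_interruption)) {
    out <- merge_compound(out, max_interruption)
  } else {
    out$n_members <- 1L
  }
  out
}

#' Summary tables of a mined SSR set
#'
#' @param records SSR tibble from [mine_ssrs()] or [find_perfect_ssrs()].
#' @return An object of class `ssr_summary`: a list of tibbles
#'   * `by_type` — counts and percentages of mono- to hexanucleotide and
#'     compound loci (denominator: all loci including compound);
#'   * `by_class` — counts of canonical motif classes within each unit
#'     length;
#'   * `repeat_hist` — perfect-locus counts by repeat number binned
#'     5,6,7,8,9,>=10.
#' @export
summarize_ssrs <- function(records) {
  type_levels <- c("mono", "di", "tri", "tetra", "penta", "hexa", "compound")
  total <- nrow(records)
  type_of <- ifelse(records$kind == "compound", "compound",
    type_levels[records$unit_length]
  )
  by_type <- tibble::tibble(type = factor(type_of, levels = type_levels)) |>
    dplyr::count(.data$type, .drop = FALSE, name = "n") |>
    dplyr::mutate(
      type = as.character(.data$type),
      pct = if (total == 0) 0 else round_half_up(100 * .data$n / total, 2)
    )

  perfect <- records[records$kind == "perfect", ]
  by_class <- perfect |>
    dplyr::count(.data$unit_length, .data$canonical_class, name = "n") |>
    dplyr::arrange(.data$unit_length, .data$canonical_class) |>
    dplyr::mutate(
      pct = if (total == 0) 0 else round_half_up(100 * .data$n / total, 2)
    )

  bins <- c("5", "6", "7", "8", "9", ">=10")
  bin_of <- ifelse(perfect$repeat_count >= 10, ">=10",
    as.character(perfect$repeat_count)
  )
  bin_of <- bin_of[perfect$repeat_count >= 5]
  repeat_hist <- tibble::tibble(repeats = factor(bin_of, levels = bins)) |>
    dplyr::count(.data$repeats, .drop = FALSE, name = "n") |>
    dplyr::mutate(
      repeats = as.character(.data$repeats),
      pct = if (nrow(perfect) == 0) {
        0
      } else {
        round_half_up(100 * .data$n / nrow(perfect), 2)
      }
    )

  structure(
    list(by_type = by_type, by_class = by_class, repeat_hist = repeat_hist),
    class = "ssr_summary"
  )
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat("<ssr_summary>\n  loci by type:\n")
  print(x$by_type)
  cat("  repeat-count distribution (perfect loci):\n")
  print(x$repeat_hist)
  invisible(x)
}

#' @describeIn summarize_ssrs Bar charts of the type distribution and the
#'   repeat-count histogram.
#' @param object,... `autoplot` method arguments.
#' @method autoplot ssr_summary
#' @export
autoplot.ssr_summary <- function(object, ...) {
  d <- dplyr::bind_rows(
    dplyr::transmute(object$by_type,
      panel = "SSR type", x = factor(.data$type, levels = .data$type),
      n = .data$n
    ),
    dplyr::transmute(object$repeat_hist,
      panel = "Repeat count", x = factor(.data$repeats, levels = .data$repeats),
      n = .data$n
    )
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Number of SSR loci") +
    ggplot2::theme_minimal()
}
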