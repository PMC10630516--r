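genotype_token <- function(a1, a2) {
  ifelse(is.na(a1), "-/-", paste0(a1, "/", a2))
}

profile_strings <- function(g, markers) {
  tab <- tibble::as_tibble(g)
  tab <- tab[tab$locus %in% markers, ]
  tab$locus <- factor(tab$locus, levels = markers)
  tab <- tab[order(match(tab$individual, gt_individuals(g)), tab$locus), ]
  tok <- genotype_token(tab$allele_1, tab$allele_2)
  vapply(
    split(tok, factor(tab$individual, levels = gt_individuals(g))),
    paste,
    character(1),
    collapse = "|"
  )
}

#' Count accessions distinguished by a marker subset
#'
#' An individual is distinguished when its multilocus profile over the
#' subset (unordered allele pairs; a missing genotype is its own symbol) is
#' unique among all individuals. The rate is the percentage of
#' distinguished individuals, rounded to 2 decimals.
#'
#' @param g A genotype table.
#' @param markers Character vector of locus names (subset of `gt_loci(g)`).
#' @return A one-row tibble with columns `n_markers`, `n_distinguished`,
#'   `rate`.
#' @export
count_distinguished <- function(g, markers) {
  g <- as_genotypes(g)
  if (length(markers) == 0) {
    return(tibble::tibble(n_markers = 0L, n_distinguished = 0L, rate = 0))
  }
  unknown <- setdiff(markers, gt_loci(g))
  if (length(unknown) > 0) {
    stop("unknown marker(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  prof <- profile_strings(g, markers)
  n_dist <- sum(table(prof)[prof] == 1)
  tibble::tibble(
    n_markers = length(markers),
    n_distinguished = as.integer(n_dist),
    rate = round_half_up(100 * n_dist / length(prof), 2)
  )
}

#' Greedy PIC-ranked fingerprinting panel
#'
#' Builds the discrimination panel the way marker panels for cultivar
#' fingerprinting are assembled: candidate markers are sorted by
#' informativeness (descending PIC, ties broken by higher Na then by
#' name) and appended one by one — no skipping — until every accession has
#' a unique multilocus profile or candidates run out (then a warning is
#' emitted and the final rate stays below 100%). With
#' `allow_skip = TRUE`, a ranked marker that does not increase the
#' distinguished count is skipped instead.
#'
#' @param g A genotype table.
#' @param ranking Optional tibble with columns `locus`, `PIC` (and
#'   optionally `Na`); computed from [diversity_table()] when omitted.
#' @param allow_skip Skip markers that add no discrimination.
#' @return An object of class `ssr_panel`: list with `steps` (tibble:
#'   `step`, `marker`, `markers` — cumulative `"+"`-joined label,
#'   `n_distinguished`, `rate`), `markers` (the panel, in order) and
#'   `letters` (tibble `marker`, `letter`: first marker `"A"`, second
#'   `"B"`, ...).
#' @export
greedy_panel <- function(g, ranking = NULL, allow_skip = FALSE) {
  g <- as_genotypes(g)
  if (is.null(ranking)) {
    div <- diversity_table(g, by = "locus")
    ranking <- div[div$locus != "Mean", c("locus", "Na", "PIC")]
  }
  if (!all(c("locus", "PIC") %in% names(ranking))) {
    stop("ranking needs columns locus and PIC", call. = FALSE)
  }
  if (!all(gt_loci(g) %in% ranking$locus)) {
    stop("ranking must cover every candidate locus", call. = FALSE)
  }
  if (!"Na" %in% names(ranking)) ranking$Na <- 0
  ranking <- dplyr::arrange(
    ranking, dplyr::desc(.data$PIC), dplyr::desc(.data$Na), .data$locus
  )

  n <- n_individuals(g)
  chosen <- character(0)
  steps <- list()
  last_count <- -1L
  for (m in ranking$locus) {
    cd_try <- count_distinguished(g, c(chosen, m))
    if (allow_skip && cd_try$n_distinguished <= last_count) next
    chosen <- c(chosen, m)
    steps[[length(steps) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(
        step = length(chosen), marker = m,
        markers = paste(chosen, collapse = "+")
      ),
      cd_try[c("n_distinguished", "rate")]
    )
    last_count <- cd_try$n_distinguished
    if (cd_try$n_distinguished == n) break
  }
  steps <- dplyr::bind_rows(steps)
  if (utils::tail(steps$n_distinguished, 1) < n) {
    warning("panel exhausted all candidates at ",
      utils::tail(steps$rate, 1), "% discrimination"
    )
  }
  structure(
    list(
      steps = steps,
      markers = chosen,
      letters = tibble::tibble(
        marker = chosen, letter = LETTERS[seq_along(chosen)]
      )
    ),
    class = "ssr_panel"
  )
}

#' @export
print.ssr_panel <- function(x, ...) {
  cat(sprintf(
    "<ssr_panel> %d markers (%s), final discrimination %.2f%%\n",
    length(x$markers), paste(x$markers, collapse = "+"),
    utils::tail(x$steps$rate, 1)
  ))
  print(x$steps)
  invisible(x)
}

#' @method tidy ssr_panel
#' @export
tidy.ssr_panel <- function(x, ...) x$steps

#' @method glance ssr_panel
#' @export
glance.ssr_panel <- function(x, ...) {
  tibble::tibble(
    n_markers = length(x$markers),
    n_distinguished = utils::tail(x$steps$n_distinguished, 1),
    rate = utils::tail(x$steps$rate, 1)
  )
}

#' @method autoplot ssr_panel
#' @export
autoplot.ssr_panel <- function(object, ...) {
  d <- object$steps
  ggplot2::ggplot(d, ggplot2::aes(.data$step, .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(
      breaks = d$step, labels = d$marker
    ) +
    ggplot2::labs(
      x = "Marker added", y = "Differentiation rate (%)"
    ) +
    ggplot2::theme_minimal()
}

#' Exhaustive minimal discriminating panel
#'
#' Brute-force search over marker subsets by increasing size (then
#' lexicographic order) for the smallest subset under which every
#' accession's multilocus profile is unique. Intended as a reference for
#' the greedy panel on small problems; `max_size` is capped at 8 as a
#' combinatorial guard.
#'
#' @param g A genotype table.
#' @param max_size Largest subset size to try (<= 8).
#' @return Character vector of locus names, or `NA` if no subset of size
#'   `<= max_size` discriminates fully.
#' @export
minimal_panel_bruteforce <- function(g, max_size = 8) {
  if (max_size > 8) {
    stop("max_size is capped at 8 (exhaustive search)", call. = FALSE)
  }
  g <- as_genotypes(g)
  loci <- sort(gt_loci(g))
  n <- n_individuals(g)
  for (size in seq_len(min(max_size, length(loci)))) {
    subsets <- utils::combn(loci, size, simplify = FALSE)
    for (s in subsets) {
      if (count_distinguished(g, s)$n_distinguished == n) {
        return(s)
      }
    }
  }
  NA_character_
}

#' Fingerprint payload strings
#'
#' One deterministic text payload per accession, the content a QR code
#' would carry: the accession name followed by per-panel-letter genotype
#' fields, e.g. `"ind1 A:120/124;B:-/-"`. Alleles are ascending within a
#' field and a missing genotype renders `-/-`. When the panel fully
#' discriminates the accessions, payloads are unique.
#'
#' @param g A genotype table.
#' @param panel An [greedy_panel()] result, or a character vector of
#'   markers (letters assigned in order).
#' @return A tibble with columns `individual`, `payload`.
#' @export
fingerprint_payloads <- function(g, panel) {
  g <- as_genotypes(g)
  markers <- if (inherits(panel, "ssr_panel")) panel$markers else panel
  letters_map <- LETTERS[seq_along(markers)]
  tab <- tibble::as_tibble(g)
  tab <- tab[tab$locus %in% markers, ]
  tab$letter <- letters_map[match(tab$locus, markers)]
  tab <- tab[order(
    match(tab$individual, gt_individuals(g)), tab$letter
  ), ]
  fields <- paste0(
    tab$letter, ":", genotype_token(tab$allele_1, tab$allele_2)
  )
  payloads <- vapply(
    split(fields, factor(tab$individual, levels = gt_individuals(g))),
    paste,
    character(1),
    collapse = ";"
  )
  tibble::tibble(
    individual = gt_individuals(g),
    payload = paste(gt_individuals(g), unname(payloads))
  )
}
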