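#' Read a diploid codominant genotype table
#'
#' Two dialects are supported:
#'
#' * `"genalex-csv"` — the GenAlEx codominant export: row 1 holds
#'   `n_loci, n_samples, n_pops, size_1, ..., size_k`; row 2 a title followed
#'   by blanks and then the population names (one per population, aligned
#'   under the sizes); row 3 the column header (`sample, pop`, then two
#'   columns per locus of which the first carries the locus name); data rows
#'   follow with two allele columns per locus. Missing genotypes are coded
#'   `0` in both allele columns.
#' * `"long-csv"` — a plain long table with header
#'   `individual,population,locus,allele1,allele2`; missing genotypes are
#'   blank or `NA` cells.
#'
#' Inside the package a missing call is always the `NA` sentinel; the
#' GenAlEx `0` code exists only in serialized form.
#'
#' @param path Path to the CSV file.
#' @param dialect `"genalex-csv"` or `"long-csv"`.
#' @return A [genotypes][as_genotypes] tibble.
#' @seealso [write_genotypes()], [write_structure_input()]
#' @export
read_genotypes <- function(path, dialect = c("genalex-csv", "long-csv")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    "genalex-csv" = read_genalex_csv(path),
    "long-csv" = read_long_csv(path)
  )
}

split_csv_line <- function(line) {
  out <- strsplit(line, ",", fixed = TRUE)[[1]]
  # trailing empty fields are dropped by strsplit; keep them
  n_commas <- lengths(regmatches(line, gregexpr(",", line, fixed = TRUE)))
  if (length(out) < n_commas + 1) {
    out <- c(out, rep("", n_commas + 1 - length(out)))
  }
  trimws(out)
}

read_genalex_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) <= 3]
  if (length(lines) < 4) {
    stop("GenAlEx format error at line 1: file must have 3 header rows and ",
      "at least one data row",
      call. = FALSE
    )
  }

  h1 <- split_csv_line(lines[1])
  h1_num <- suppressWarnings(as.integer(h1))
  if (length(h1) < 3 || anyNA(h1_num[1:3])) {
    stop("GenAlEx format error at line 1: expected integer fields ",
      "'n_loci,n_samples,n_pops,<pop sizes>'",
      call. = FALSE
    )
  }
  n_loci_decl <- h1_num[1]
  n_samples_decl <- h1_num[2]
  n_pops_decl <- h1_num[3]
  pop_sizes <- h1_num[seq(4, length.out = n_pops_decl)]
  if (length(pop_sizes) < n_pops_decl || anyNA(pop_sizes)) {
    stop("GenAlEx format error at line 1: declared ", n_pops_decl,
      " populations but population sizes are incomplete",
      call. = FALSE
    )
  }
  if (sum(pop_sizes) != n_samples_decl) {
    stop("GenAlEx consistency error: population sizes sum to ",
      sum(pop_sizes), " but line 1 declares ", n_samples_decl, " samples",
      call. = FALSE
    )
  }

  h2 <- split_csv_line(lines[2])
  pop_names <- h2[seq(4, length.out = n_pops_decl)]
  pop_names <- pop_names[!is.na(pop_names)]
  if (length(pop_names) < n_pops_decl || any(pop_names == "")) {
    stop("GenAlEx format error at line 2: expected ", n_pops_decl,
      " population names from column 4 onward",
      call. = FALSE
    )
  }

  h3 <- split_csv_line(lines[3])
  locus_cols <- h3[-(1:2)]
  loci <- locus_cols[seq(1, length.out = n_loci_decl, by = 2)]
  if (length(locus_cols) < 2 * n_loci_decl || anyNA(loci) || any(loci == "")) {
    stop("GenAlEx format error at line 3: header declares ", n_loci_decl,
      " loci so ", 2 * n_loci_decl, " allele columns are required",
      call. = FALSE
    )
  }

  data_lines <- lines[-(1:3)]
  data_lines <- data_lines[!grepl("^\\s*$", data_lines) &
    !grepl("^,*$", data_lines)]
  if (length(data_lines) != n_samples_decl) {
    stop("GenAlEx consistency error: line 1 declares ", n_samples_decl,
      " samples but ", length(data_lines), " data rows were found",
      call. = FALSE
    )
  }

  pop_of_row <- rep(pop_names, times = pop_sizes)
  rows <- vector("list", length(data_lines))
  for (i in seq_along(data_lines)) {
    f <- split_csv_line(data_lines[i])
    if (length(f) != 2 + 2 * n_loci_decl) {
      stop("GenAlEx data error at line ", i + 3, " (individual '", f[1],
        "'): expected ", 2 + 2 * n_loci_decl, " fields (two allele columns ",
        "per locus), found ", length(f),
        call. = FALSE
      )
    }
    alleles <- suppressWarnings(as.integer(f[-(1:2)]))
    if (anyNA(alleles)) {
      bad <- which(is.na(alleles))[1]
      stop("GenAlEx data error at line ", i + 3, ": non-integer allele for ",
        "individual '", f[1], "' at locus '", loci[ceiling(bad / 2)], "'",
        call. = FALSE
      )
    }
    rows[[i]] <- tibble::tibble(
      individual = f[1],
      population = pop_of_row[i],
      locus = loci,
      allele_1 = alleles[seq(1, 2 * n_loci_decl, by = 2)],
      allele_2 = alleles[seq(2, 2 * n_loci_decl, by = 2)]
    )
  }
  out <- dplyr::bind_rows(rows)

  # 0 is the serialized missing code; a 0 paired with a real allele is a
  # half call and rejected by validation
  zero <- !is.na(out$allele_1) & out$allele_1 == 0L & out$allele_2 == 0L
  out$allele_1[zero] <- NA_integer_
  out$allele_2[zero] <- NA_integer_
  half0 <- xor(out$allele_1 %in% 0L, out$allele_2 %in% 0L)
  if (any(half0)) {
    i <- which(half0)[1]
    stop("GenAlEx data error: individual '", out$individual[i],
      "' at locus '", out$locus[i], "' has one allele coded 0 (missing) and ",
      "one real allele",
      call. = FALSE
    )
  }
  as_genotypes(out)
}

read_long_csv <- function(path) {
  tab <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  nm <- tolower(names(tab))
  names(tab) <- nm
  if ("allele1" %in% nm) {
    tab <- dplyr::rename(tab, allele_1 = "allele1", allele_2 = "allele2")
  }
  required <- c("individual", "population", "locus", "allele_1", "allele_2")
  if (!all(required %in% names(tab))) {
    stop("long-csv format error: header must contain columns ",
      "individual,population,locus,allele1,allele2",
      call. = FALSE
    )
  }
  blank_na <- function(x) ifelse(x %in% c("", "NA"), NA_character_, x)
  tab <- dplyr::mutate(tab,
    allele_1 = suppressWarnings(as.integer(blank_na(.data$allele_1))),
    allele_2 = suppressWarnings(as.integer(blank_na(.data$allele_2)))
  )
  as_genotypes(tab)
}

#' Write a genotype table
#'
#' Serializes a genotype table in either dialect accepted by
#' [read_genotypes()]. In the GenAlEx dialect individuals are grouped by
#' population (stable within population) because the format stores
#' population membership as consecutive block sizes; the long dialect
#' preserves row order exactly.
#'
#' @param g A genotype table.
#' @param path Output file path.
#' @param dialect `"genalex-csv"` or `"long-csv"`.
#' @param title Title string placed in the GenAlEx header (row 2).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, dialect = c("genalex-csv", "long-csv"),
                            title = "ssrpopgen export") {
  g <- as_genotypes(g)
  dialect <- match.arg(dialect)
  if (dialect == "long-csv") {
    readr::write_csv(
      dplyr::rename(tibble::as_tibble(g),
        allele1 = "allele_1", allele2 = "allele_2"
      ),
      path, na = ""
    )
    return(invisible(path))
  }

  loci <- gt_loci(g)
  pops_of <- gt_populations(g)
  pop_levels <- unique(unname(pops_of))
  inds <- gt_individuals(g)
  inds <- inds[order(match(pops_of[inds], pop_levels))]
  sizes <- as.vector(table(factor(pops_of[inds], levels = pop_levels)))

  wide <- tibble::as_tibble(g) |>
    dplyr::mutate(
      allele_1 = ifelse(is.na(.data$allele_1), 0L, .data$allele_1),
      allele_2 = ifelse(is.na(.data$allele_2), 0L, .data$allele_2)
    )
  key <- paste(wide$individual, wide$locus, sep = "\r")
  a1 <- stats::setNames(wide$allele_1, key)
  a2 <- stats::setNames(wide$allele_2, key)

  n_field <- 2 + 2 * length(loci)
  pad <- function(x) c(x, rep("", max(0, n_field - length(x))))
  h1 <- pad(c(length(loci), length(inds), length(pop_levels), sizes))
  h2 <- pad(c(title, "", "", pop_levels))
  h3 <- pad(c("sample", "pop", as.vector(rbind(loci, ""))))
  body <- vapply(inds, function(ind) {
    k <- paste(ind, loci, sep = "\r")
    paste(c(ind, pops_of[[ind]], as.vector(rbind(a1[k], a2[k]))),
      collapse = ","
    )
  }, character(1))
  writeLines(
    c(paste(h1, collapse = ","), paste(h2, collapse = ","),
      paste(h3, collapse = ","), body),
    path
  )
  invisible(path)
}

#' Export genotypes in STRUCTURE two-row format
#'
#' Writes the integer input format consumed by STRUCTURE: two rows per
#' individual (one allele per row), columns `label`, `pop` (1-based integer
#' in first-appearance order of the population labels), then one column per
#' locus. Missing alleles are coded `-9`.
#'
#' @param g A genotype table.
#' @param path Output path, or `NULL` to return the lines.
#' @return Character vector of lines, invisibly when `path` is given.
#' @export
write_structure_input <- function(g, path = NULL) {
  g <- as_genotypes(g)
  loci <- gt_loci(g)
  pops_of <- gt_populations(g)
  pop_int <- stats::setNames(
    match(unname(pops_of), unique(unname(pops_of))), names(pops_of)
  )
  tab <- tibble::as_tibble(g)
  key <- paste(tab$individual, tab$locus, sep = "\r")
  a1 <- stats::setNames(ifelse(is.na(tab$allele_1), -9L, tab$allele_1), key)
  a2 <- stats::setNames(ifelse(is.na(tab$allele_2), -9L, tab$allele_2), key)
  lines <- unlist(lapply(gt_individuals(g), function(ind) {
    k <- paste(ind, loci, sep = "\r")
    c(
      paste(c(ind, pop_int[[ind]], a1[k]), collapse = "\t"),
      paste(c(ind, pop_int[[ind]], a2[k]), collapse = "\t")
    )
  }))
  if (is.null(path)) {
    return(lines)
  }
  writeLines(lines, path)
  invisible(lines)
}

#' Read a STRUCTURE run-likelihood table
#'
#' Reads a CSV with columns `K` (cluster count), `run` (replicate index) and
#' `lnPD` (the estimated ln-probability of the data, LnP(D)), the input of
#' [evanno_deltak()].
#'
#' @param path CSV path.
#' @return A tibble with columns `K`, `run`, `lnPD`.
#' @export
read_structure_runs <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("k", "run", "lnpd") %in% names(tab))) {
    stop("structure-runs format error: header must contain K,run,lnPD",
      call. = FALSE
    )
  }
  tibble::tibble(
    K = as.integer(tab$k),
    run = as.integer(tab$run),
    lnPD = as.numeric(tab$lnpd)
  )
}
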