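fmt3 <- function(x) {
  ifelse(is.na(x), "", sprintf("%.3f", round_half_up(x, 3)))
}

write_rounded_csv <- function(tab, path, digits = 3) {
  out <- dplyr::mutate(tab, dplyr::across(
    dplyr::where(is.numeric),
    ~ round_half_up(.x, digits)
  ))
  readr::write_csv(out, path, na = "")
  path
}

#' Run the full microsatellite analysis pipeline
#'
#' Orchestrates the whole analysis chain on one genotype table: per-locus
#' and per-population diversity statistics, per-locus F-statistics and gene
#' flow, pairwise population Fst/Nm and Nei identity/distance matrices, a
#' UPGMA tree and PCoA on individual shared-allele distances, optional
#' Evanno delta-K post-processing of a STRUCTURE run table, and the greedy
#' PIC-ranked fingerprinting panel with per-accession payloads.
#'
#' Outputs are written with fixed filenames into `outdir`:
#' `diversity_by_locus.csv`, `diversity_by_population.csv`, `fstats.csv`,
#' `pairwise_fst_nm.csv`, `nei_gi_gd.csv`, `tree.nwk`, `pcoa.csv`,
#' `deltak.csv` (only when a runs table is supplied), `panel.csv`,
#' `fingerprints.txt`, plus `run_log.txt` recording package version, seed
#' and row counts. Table cells are rounded half-up to 3 decimals
#' (percentages to 2); identical inputs and seed give byte-identical
#' outputs. Any stage error aborts the run, removes partial outputs, and
#' names the failing stage.
#'
#' @param genotypes A genotype table, or a path read with
#'   [read_genotypes()].
#' @param outdir Output directory (created if absent).
#' @param dialect Genotype file dialect when `genotypes` is a path.
#' @param structure_runs Optional path to (or tibble of) a STRUCTURE
#'   run-likelihood table for delta-K.
#' @param seed Seed recorded in the log (the pipeline itself is
#'   deterministic).
#' @return Invisibly, a named list of the in-memory results.
#' @export
run_pipeline <- function(genotypes, outdir,
                         dialect = c("genalex-csv", "long-csv"),
                         structure_runs = NULL, seed = 1L) {
  dialect <- match.arg(dialect)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  log_lines <- c(
    sprintf("ssrpopgen %s", as.character(utils::packageVersion("ssrpopgen"))),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("started: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  )
  emit <- function(name) {
    written <<- c(written, file.path(outdir, name))
    file.path(outdir, name)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }

  g <- stage("read-genotypes", {
    if (is.character(genotypes)) {
      read_genotypes(genotypes, dialect)
    } else {
      as_genotypes(genotypes)
    }
  })
  log_lines <- c(log_lines, sprintf(
    "genotypes: %d individuals x %d loci", n_individuals(g), n_loci(g)
  ))

  div_locus <- stage("diversity-by-locus", diversity_table(g, "locus"))
  write_rounded_csv(div_locus, emit("diversity_by_locus.csv"))

  div_pop <- stage(
    "diversity-by-population", diversity_table(g, "population")
  )
  write_rounded_csv(div_pop, emit("diversity_by_population.csv"))

  multi_pop <- length(unique(unname(gt_populations(g)))) >= 2
  fst_tab <- pw <- nei <- NULL
  if (multi_pop) {
    fst_tab <- stage("fstats", fstats_by_locus(g))
    write_rounded_csv(fst_tab, emit("fstats.csv"))
    pw <- stage("pairwise-fst", pairwise_fst(g))
    write_rounded_csv(pw, emit("pairwise_fst_nm.csv"))
    nei <- stage("nei-distance", nei_identity_distance(g))
    write_rounded_csv(nei, emit("nei_gi_gd.csv"))
  } else {
    log_lines <- c(
      log_lines,
      "single population: F-statistics and distance matrices skipped"
    )
  }

  dmat <- stage("individual-distances", individual_distances(g))
  tree <- stage("upgma", upgma(dmat))
  ape::write.tree(tree, emit("tree.nwk"))

  ord <- stage("pcoa", pcoa(dmat))
  pcoa_tab <- ord$points
  attr(pcoa_tab, "var_pct") <- NULL
  pcoa_out <- dplyr::bind_rows(
    dplyr::mutate(
      pcoa_tab,
      dplyr::across(dplyr::where(is.numeric), ~ round_half_up(.x, 3))
    ),
    dplyr::bind_cols(
      tibble::tibble(individual = "pct_variance"),
      tibble::as_tibble(as.list(stats::setNames(
        round_half_up(ord$var_pct, 2), paste0("Axis", seq_along(ord$var_pct))
      )))
    )
  )
  readr::write_csv(pcoa_out, emit("pcoa.csv"), na = "")

  dk <- NULL
  if (!is.null(structure_runs)) {
    runs <- stage("read-structure-runs", {
      if (is.character(structure_runs)) {
        read_structure_runs(structure_runs)
      } else {
        structure_runs
      }
    })
    dk <- stage("evanno-deltak", evanno_deltak(runs))
    write_rounded_csv(tidy(dk), emit("deltak.csv"))
    log_lines <- c(log_lines, sprintf("best K: %d", attr(dk, "best_K")))
  } else {
    log_lines <- c(log_lines, "no STRUCTURE runs table: deltak.csv skipped")
  }

  panel <- stage("greedy-panel", suppressWarnings(
    greedy_panel(g, ranking = div_locus[
      div_locus$locus != "Mean", c("locus", "Na", "PIC")
    ])
  ))
  readr::write_csv(
    dplyr::transmute(panel$steps,
      `Primer combination` = .data$markers,
      `Number distinguished` = .data$n_distinguished,
      `Differentiation rate` = sprintf("%.2f", .data$rate)
    ),
    emit("panel.csv")
  )

  payloads <- stage(
    "fingerprints", fingerprint_payloads(g, panel)
  )
  writeLines(payloads$payload, emit("fingerprints.txt"))

  log_lines <- c(log_lines, sprintf(
    "panel: %d markers, %.2f%% discrimination",
    length(panel$markers), utils::tail(panel$steps$rate, 1)
  ))
  log_lines <- c(
    log_lines,
    sprintf("outputs: %d files", length(written) + 1L)
  )
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  ok <- TRUE
  invisible(list(
    genotypes = g, diversity_by_locus = div_locus,
    diversity_by_population = div_pop, fstats = fst_tab,
    pairwise_fst = pw, nei = nei, tree = tree, pcoa = ord,
    deltak = dk, panel = panel, fingerprints = payloads
  ))
}
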