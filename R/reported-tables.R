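#' Reported marker statistics for the Ailanthus EST-SSR study system
#'
#' The package ships the published summary statistics of the 19 polymorphic
#' EST-SSR markers genotyped on 120 *Ailanthus altissima* var.
#' *erythrocarpa* accessions from 7 natural populations — the system whose
#' analysis chain this package reimplements. The underlying genotype matrix
#' is unpublished, but the summary tables are exact functions of each other
#' under the implemented estimators (e.g. `He = 1 - 1/Ne`,
#' `F = 1 - Ho/He`, `uHe = He * 2N/(2N - 1)`, `Nm = (1 - Fst)/(4 Fst)`,
#' `GD = -ln(GI)`), which makes them useful consistency references.
#'
#' @param which One of `"diversity"` (per-locus N, Na, Ne, I, Ho, He, uHe,
#'   F, PIC), `"fstats"` (per-locus Fis, Fit, Fst, Nm) or `"nei"` (pairwise
#'   population GI/GD).
#' @return A tibble.
#' @examples
#' rep_div <- reported_marker_stats("diversity")
#' all.equal(rep_div$He, 1 - 1 / rep_div$Ne, tolerance = 0.002)
#' @export
reported_marker_stats <- function(which = c("diversity", "fstats", "nei")) {
  which <- match.arg(which)
  file <- switch(which,
    diversity = "ailanthus_locus_diversity.csv",
    fstats = "ailanthus_locus_fstats.csv",
    nei = "ailanthus_nei_gi_gd.csv"
  )
  readr::read_csv(
    system.file("extdata", file, package = "ssrpopgen", mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE
  )
}
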