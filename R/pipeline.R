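# End-to-end convenience wrappers: simulate -> qc -> homerange -> (usability,
# morpho/PCA) -> one-row-per-bear table, and the equivalent path from a fixes
# CSV on disk.

#' Run the full pipeline on a synthetic population
#'
#' Simulates a population, applies the QC cascade, estimates home ranges,
#' (optionally) screens KUD usability, fits the PCA, and assembles the
#' analytical table.
#'
#' @param spec a [population_spec()].
#' @param mp_template a [movement_params()] template.
#' @param em an [error_model()].
#' @param compute_kud estimate kernel ranges (slower) in addition to MCP.
#' @param assess_kud run the five usability criteria per bear (requires
#'   `compute_kud`).
#' @param pca_preset trait preset for [fit_pca()], or `NULL` to skip PCA.
#' @param min_fixes minimum usable fixes for home-range estimation.
#' @return list: `bears` (analytical table), `home_ranges`, `qc_reports`,
#'   `usability`, `truth`, `truth_fixes`, `pca`.
#' @export
run_pipeline <- function(spec = population_spec(),
                         mp_template = movement_params(),
                         em = error_model(),
                         compute_kud = FALSE, assess_kud = FALSE,
                         pca_preset = "four", min_fixes = 30) {
  sim <- simulate_population(spec, mp_template, em)
  trajs <- split(sim$fixes, sim$fixes$animal_id)
  qc <- qc_trajectories(trajs)
  hr <- estimate_home_ranges(qc$clean, min_fixes = min_fixes,
                             compute_kud = compute_kud)
  usab <- NULL
  if (assess_kud && compute_kud) {
    proj <- attr(hr, "projection")
    usab <- lapply(qc$clean[hr$animal_id[hr$excluded_reason == ""]],
                   assess_usability, proj = proj)
  }
  pca <- if (!is.null(pca_preset)) fit_pca(sim$morpho, pca_traits(pca_preset)) else NULL
  bears <- assemble_table(hr, usab, sim$morpho, pca)
  bears <- bears[bears$excluded_reason %in% c("", NA), , drop = FALSE]
  list(bears = bears, home_ranges = hr, qc_reports = qc$reports,
       usability = usab, truth = sim$truth, truth_fixes = sim$truth_fixes,
       pca = pca)
}

#' Median MCP95 of a deposited telemetry data set
#'
#' Runs the QC cascade and MCP95 estimation on a fixes CSV in the documented
#' column layout and returns the median home-range area across bears, the
#' quantity summarising population-level space use in the study data.
#'
#' @param fixes_csv path to the deposited fixes CSV.
#' @param min_fixes minimum usable fixes per bear.
#' @return list: `median_mcp_km2`, `n_bears`, `home_ranges`.
#' @export
reproduce_deposited_median <- function(fixes_csv, min_fixes = 30) {
  trajs <- parse_fixes(fixes_csv)
  qc <- qc_trajectories(trajs)
  hr <- estimate_home_ranges(qc$clean, min_fixes = min_fixes, compute_kud = FALSE)
  ok <- hr$excluded_reason == ""
  list(median_mcp_km2 = stats::median(hr$mcp_km2[ok]),
       n_bears = sum(ok), home_ranges = hr)
}
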