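# Morphometric summaries: trait correlation matrix, correlation-matrix PCA
# with a sign convention that orients the general size axis positively, and
# assembly of the one-row-per-bear analytical table.

#' Pairwise-complete Pearson correlations among traits
#'
#' @param records data.frame with one row per bear.
#' @param traits character vector of trait columns.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
trait_correlations <- function(records, traits) {
  X <- as.matrix(records[, traits, drop = FALSE])
  npairs <- crossprod(!is.na(X))
  if (any(npairs[upper.tri(npairs)] < 3))
    stop("trait_correlations requires >= 3 pairwise-complete records per pair",
         call. = FALSE)
  stats::cor(X, use = "pairwise.complete.obs")
}

#' Four- and eight-trait PCA presets
#'
#' The four-trait preset (mass, body length, head length, tail length) is the
#' default; the eight-trait preset adds chest circumference, shoulder height
#' and front/hind paw widths (left/right averaged when both present).
#' @param preset `"four"` or `"eight"`.
#' @export
pca_traits <- function(preset = c("four", "eight")) {
  preset <- match.arg(preset)
  if (preset == "four")
    c("mass_kg", "body_length_cm", "head_length_cm", "tail_length_cm")
  else
    c("mass_kg", "body_length_cm", "chest_circ_cm", "shoulder_height_cm",
      "front_paw_w_l_cm", "front_paw_w_r_cm", "hind_paw_w_l_cm", "hind_paw_w_r_cm")
}

#' Correlation-matrix PCA of morphometric traits
#'
#' Complete-case records are standardised (mean 0, SD 1, n-1 denominator) and
#' decomposed; components are ordered by eigenvalue. Any component whose
#' loading sum is negative is flipped so a general size axis loads
#' positively.
#'
#' @param records data.frame with one row per bear (`animal_id` column).
#' @param traits trait columns to include.
#' @return object of class `pca_result`: `trait_names`, `loadings` (trait x
#'   component, orthonormal columns), `scores` (complete-case bears x
#'   component, rownames = animal_id), `explained_pct`, `n_complete`.
#' @export
fit_pca <- function(records, traits = pca_traits("four")) {
  X <- as.matrix(records[, traits, drop = FALSE])
  cc <- stats::complete.cases(X)
  n <- sum(cc)
  if (n < length(traits) + 1) {
    miss_per_trait <- colSums(is.na(X))
    stop("fit_pca: only ", n, " complete cases for ", length(traits),
         " traits; missing counts: ",
         paste(names(miss_per_trait), miss_per_trait, sep = "=", collapse = ", "),
         call. = FALSE)
  }
  Xc <- X[cc, , drop = FALSE]
  pr <- stats::prcomp(Xc, center = TRUE, scale. = TRUE)
  flip <- ifelse(colSums(pr$rotation) < 0, -1, 1)
  loadings <- sweep(pr$rotation, 2, flip, `*`)
  scores <- sweep(pr$x, 2, flip, `*`)
  rownames(scores) <- records$animal_id[cc]
  ev <- pr$sdev^2
  structure(list(trait_names = traits, loadings = loadings, scores = scores,
                 explained_pct = 100 * ev / sum(ev), n_complete = n),
            class = "pca_result")
}

#' Assemble the one-row-per-bear analytical table
#'
#' Joins home-range estimates, usability verdicts, morphometrics and PC
#' scores by `animal_id`. `kud_km2` is nulled for bears failing usability
#' (they are retained for MCP); `log_mcp` is the natural log of `mcp_km2`.
#'
#' @param home_ranges output of [estimate_home_ranges()].
#' @param usability named list of [assess_usability()] reports (or `NULL`).
#' @param morpho morphometric records.
#' @param pca a [fit_pca()] result (or `NULL` to skip PC scores).
#' @return data.frame of bear records with a `morpho_missing` flag.
#' @export
assemble_table <- function(home_ranges, usability = NULL, morpho = NULL, pca = NULL) {
  out <- as.data.frame(home_ranges)
  attr(out, "uds") <- NULL
  if (!is.null(usability)) {
    failed <- vapply(usability, function(r) !isTRUE(r$overall_pass), logical(1))
    failed_ids <- vapply(usability, `[[`, character(1), "animal_id")[failed]
    out$kud_km2[out$animal_id %in% failed_ids] <- NA_real_
    out$kud_usable <- !(out$animal_id %in% failed_ids) & !is.na(out$kud_km2)
  }
  if (!is.null(morpho)) {
    out <- merge(out, morpho, by = "animal_id", all = TRUE)
    out$morpho_missing <- !(out$animal_id %in% morpho$animal_id)
  } else {
    out$morpho_missing <- TRUE
  }
  if (!is.null(pca)) {
    sc <- data.frame(animal_id = rownames(pca$scores),
                     pc1 = pca$scores[, 1],
                     pc2 = if (ncol(pca$scores) >= 2) pca$scores[, 2] else NA_real_,
                     stringsAsFactors = FALSE)
    out <- merge(out, sc, by = "animal_id", all.x = TRUE)
  }
  out$log_mcp <- ifelse(!is.na(out$mcp_km2) & out$mcp_km2 > 0, log(out$mcp_km2), NA_real_)
  if ("mass_kg" %in% names(out))
    out$log_mass <- ifelse(!is.na(out$mass_kg) & out$mass_kg > 0, log(out$mass_kg), NA_real_)
  if ("n_fixes" %in% names(out))
    out$log_n_fixes <- ifelse(out$n_fixes > 0, log(out$n_fixes), NA_real_)
  rownames(out) <- NULL
  out
}
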