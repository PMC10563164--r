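# End-to-end convenience wrapper: consolidated XLSMs -> reranked -> unique
# identifications -> observed FDR filter -> mass-error window -> reports.

#' Run the postprocessing pipeline on a consolidated XLSM table
#'
#' Reranks per spectrum, collapses to unique identifications (unique
#' amino-acid position x RNA product), filters at the observed target-decoy
#' FDR, then (optionally) refines by a mass-error window fitted on the
#' passing targets. Returns all intermediate objects plus the protein- and
#' RNA-centric summaries.
#'
#' @param xlsm Consolidated XLSM `data.table` (see [parse_search_results()]
#'   or [simulate_xlsm_table()]).
#' @param rna_sequence RNA used to prepare the sample (for the positional
#'   profile); NULL to skip.
#' @param alpha FDR threshold (default 0.01).
#' @param n_sigma Mass-error window half-width in spreads; NA disables the
#'   mass-error refinement (default 3).
#' @param out_dir Optional directory for TSV/CSV outputs.
#' @return List: `reranked`, `unique_ids`, `curve`, `cutoff`, `filtered`
#'   (post-FDR, post-refinement identifications with `q_value`),
#'   `mass_error_model` (or NULL), `site_matrix`, `rna_profile` (or NULL),
#'   `status`.
#' @export
run_pipeline <- function(xlsm, rna_sequence = NULL, alpha = 0.01,
                         n_sigma = 3, out_dir = NULL) {
  reranked <- rerank_by_scan(xlsm)
  rank1 <- filter_rank1(reranked)
  uids <- collapse_to_unique_ids(rank1)
  curve <- observed_fdr(uids$ld_score, uids$is_decoy)
  thr <- apply_fdr_threshold(curve, uids, alpha)
  filtered <- thr$ids
  # attach q-values by score lookup
  if (nrow(filtered) > 0L) {
    idx <- match(filtered$ld_score, curve$score)
    filtered$q_value <- curve$q_value[idx]
  } else {
    filtered$q_value <- numeric(0)
  }
  model <- NULL
  if (!is.na(n_sigma) && nrow(filtered) >= 20L) {
    model <- fit_mass_error_tolerance(filtered, n_sigma = n_sigma)
    filtered <- filter_by_mass_error(filtered, model)
  }
  site_mat <- site_adduct_counts(filtered)
  profile <- if (!is.null(rna_sequence)) {
    rna_position_profile(filtered, rna_sequence, normalize = TRUE)
  } else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_xlsm_table(reranked, file.path(out_dir, "all_xlsms.tsv"))
    write_fdr_curve(curve, file.path(out_dir, "fdr_curve.tsv"))
    write_summary_csv(filtered, file.path(out_dir, "summary.csv"))
  }
  list(reranked = reranked, unique_ids = uids, curve = curve,
       cutoff = thr$cutoff, filtered = filtered,
       mass_error_model = model, site_matrix = site_mat,
       rna_profile = profile, status = thr$status)
}
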