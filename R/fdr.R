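# Target-decoy FDR control at the unique-identification level: observed FDR
# with q-values, per-composition-bin transferred FDR with a fallback, and
# Percolator PIN export for external semi-supervised rescoring.

#' Observed target-decoy FDR curve with q-values
#'
#' At every observed score threshold t, FDR(t) = D(t) / T(t), where D and T
#' are the numbers of decoy and target identifications scoring at least t
#' (the monolink target-decoy convention; clipped to \[0, 1\]; thresholds
#' with T(t) = 0 report 1). The q-value of a threshold is the minimum FDR
#' over all thresholds at or below it — the smallest FDR at which an
#' identification with that score would be accepted — and is therefore
#' non-increasing in score.
#'
#' @param scores Numeric vector of identification scores (unique-ID level).
#' @param is_decoy Logical vector, same length.
#' @return Object of class `fdr_curve`: `data.table` with columns score
#'   (descending), n_target, n_decoy, fdr, q_value.
#' @examples
#' curve <- observed_fdr(c(30, 28, 25, 20, 18, 15, 19, 14),
#'                       c(rep(FALSE, 6), TRUE, TRUE))
#' @export
observed_fdr <- function(scores, is_decoy) {
  stopifnot(length(scores) == length(is_decoy),
            all(is.finite(scores)), is.logical(is_decoy))
  if (length(scores) == 0L) stop("empty input")
  if (!any(!is_decoy)) stop("no target identifications")
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  d <- is_decoy[ord]
  # counts at each unique threshold via cumulative sums
  n_at <- findInterval(-thr, -s)          # records with score >= thr
  cum_d <- cumsum(d)
  n_decoy <- cum_d[n_at]
  n_target <- n_at - n_decoy
  fdr <- ifelse(n_target == 0L, 1, pmin(n_decoy / pmax(n_target, 1L), 1))
  # q(t) = min FDR over thresholds <= t: cummin walking from low to high score
  q <- rev(cummin(rev(fdr)))
  structure(
    data.table::data.table(score = thr, n_target = n_target,
                           n_decoy = n_decoy, fdr = fdr, q_value = q),
    class = c("fdr_curve", "data.table", "data.frame"))
}

#' Filter identifications at an FDR threshold
#'
#' The score cutoff is the lowest score whose q-value is below `alpha`;
#' all target identifications scoring at or above it pass. If no score
#' qualifies, the result is empty with `status = "nothing passes"`.
#'
#' @param curve An `fdr_curve` from [observed_fdr()].
#' @param ids Identification table with `ld_score` and `is_decoy` columns.
#' @param alpha FDR threshold in (0, 1); default 0.01.
#' @param include_decoys Keep passing decoy rows too (default FALSE).
#' @return List: `ids` (filtered table), `cutoff` (score or NA), `status`
#'   (`"ok"` or `"nothing passes"`).
#' @export
apply_fdr_threshold <- function(curve, ids, alpha = 0.01,
                                include_decoys = FALSE) {
  stopifnot(inherits(curve, "fdr_curve"), alpha > 0, alpha < 1)
  ok <- curve$q_value < alpha
  # cutoff candidates are target scores: the cutoff is the score of the
  # weakest accepted identification
  if ("is_decoy" %in% names(ids)) {
    ok <- ok & curve$score %in% ids$ld_score[!ids$is_decoy]
  }
  if (!any(ok)) {
    return(list(ids = ids[0], cutoff = NA_real_, status = "nothing passes"))
  }
  cutoff <- min(curve$score[ok])
  keep <- ids$ld_score >= cutoff
  if (!include_decoys) keep <- keep & !ids$is_decoy
  list(ids = ids[keep], cutoff = cutoff, status = "ok")
}

#' Per-composition-bin transferred FDR
#'
#' For sparse modification classes the within-bin decoy count is too small
#' for a direct FDR estimate. The transferred estimate apportions the global
#' decoy count to each bin: the bin's decoy share pi_b is the slope of a
#' through-origin linear fit of the bin's cumulative unique-decoy count
#' against the global cumulative unique-decoy count, evaluated over
#' thresholds spanning the lowest `decoy_quantile` of unique decoy scores
#' (the score region where decoys are plentiful). The bin's FDR at t is then
#' `pi_b * D_global(t) / T_b(t)` and its cutoff the lowest observed score
#' with transferred FDR below `alpha`. Bins with fewer than `min_bin_decoys`
#' decoys in the fit region, or an undefined fit, fall back to the global
#' observed-FDR cutoff.
#'
#' @param ids Unique-identification table with `ld_score`, `is_decoy`, and a
#'   bin column (default `rna_composition`).
#' @param bin_col Name of the bin column.
#' @param alpha FDR threshold (default 0.01).
#' @param decoy_quantile Fraction of lowest unique decoy scores used for the
#'   fit (default 0.80).
#' @param min_bin_decoys Minimum bin decoys in the fit region for a valid
#'   transferred estimate (default 10).
#' @return `data.table` with one row per bin: bin, cutoff, method
#'   (`"transferred"` or `"fallback_observed"`), n_decoys_fit, pi.
#' @export
transferred_fdr <- function(ids, bin_col = "rna_composition", alpha = 0.01,
                            decoy_quantile = 0.80, min_bin_decoys = 10L) {
  x <- data.table::as.data.table(ids)
  stopifnot(bin_col %in% names(x), nrow(x) > 0L)
  curve <- observed_fdr(x$ld_score, x$is_decoy)
  global <- apply_fdr_threshold(curve, x, alpha)
  global_cutoff <- if (is.na(global$cutoff)) Inf else global$cutoff

  dec_scores <- sort(x$ld_score[x$is_decoy])
  bins <- sort(unique(x[[bin_col]]))
  # fit-region thresholds: the lowest decoy_quantile of unique decoy scores
  if (length(dec_scores) > 0L) {
    uds <- unique(dec_scores)
    fit_thr <- uds[uds <= stats::quantile(uds, decoy_quantile, names = FALSE)]
  } else {
    fit_thr <- numeric(0)
  }
  rows <- lapply(bins, function(b) {
    xb <- x[x[[bin_col]] == b]
    fallback <- function(n_fit, pi_b = NA_real_) data.table::data.table(
      bin = b, cutoff = global_cutoff, method = "fallback_observed",
      n_decoys_fit = n_fit, pi = pi_b)
    if (length(fit_thr) == 0L) return(fallback(0L))
    # cumulative (from below) decoy counts: decoys with score <= t
    g_cum <- vapply(fit_thr, function(t) sum(dec_scores <= t), numeric(1))
    b_dec <- sort(xb$ld_score[xb$is_decoy])
    b_cum <- vapply(fit_thr, function(t) sum(b_dec <= t), numeric(1))
    n_fit <- if (length(b_dec) > 0L) sum(b_dec <= max(fit_thr)) else 0L
    if (n_fit < min_bin_decoys || sum(g_cum^2) == 0) return(fallback(n_fit))
    pi_b <- sum(b_cum * g_cum) / sum(g_cum^2)
    if (!is.finite(pi_b) || pi_b <= 0) return(fallback(n_fit))
    # candidate cutoffs are the bin's target scores (the cutoff is the score
    # of the weakest accepted identification, as for the observed FDR)
    tb_scores <- xb$ld_score[!xb$is_decoy]
    cutoff <- Inf
    for (t in sort(unique(tb_scores))) {
      T_b <- sum(tb_scores >= t)
      D_g <- sum(x$ld_score >= t & x$is_decoy)
      if (pi_b * D_g / T_b < alpha) {
        cutoff <- t
        break
      }
    }
    data.table::data.table(bin = b, cutoff = cutoff, method = "transferred",
                           n_decoys_fit = n_fit, pi = pi_b)
  })
  data.table::rbindlist(rows)
}

#' Filter identifications by per-bin transferred cutoffs
#' @param ids Unique-identification table.
#' @param bin_thresholds Output of [transferred_fdr()].
#' @param bin_col Bin column name (default `rna_composition`).
#' @return Target rows scoring at or above their bin's cutoff.
#' @export
apply_bin_thresholds <- function(ids, bin_thresholds,
                                 bin_col = "rna_composition") {
  x <- data.table::as.data.table(ids)
  cut <- setNames(bin_thresholds$cutoff, bin_thresholds$bin)
  keep <- !x$is_decoy & x$ld_score >= cut[x[[bin_col]]]
  keep[is.na(keep)] <- FALSE
  x[keep]
}

.PIN_FIXED <- c("SpecId", "Label", "ScanNr")

#' Export rank-1 XLSMs as a Percolator PIN table
#'
#' Columns: SpecId, Label (+1 target / -1 decoy), ScanNr (light scan id),
#' the feature block — ld_score, every ingested `subscore_*` column, rna_mass
#' (the calculated peptide mass addition), rna_length, mass_error_ppm,
#' charge when present, pep_len — then Peptide in dotted notation and
#' Proteins. All features must be finite.
#'
#' @param xlsm Rank-1 XLSM table with subscore columns.
#' @param path Optional output path for the tab-separated PIN file.
#' @return The PIN `data.table` (invisibly if `path` given).
#' @export
export_pin <- function(xlsm, path = NULL) {
  x <- data.table::as.data.table(xlsm)
  if (nrow(x) == 0L) stop("empty XLSM table")
  subs <- subscore_columns(x)
  for (col in subs) {
    bad <- which(!is.finite(x[[col]]))
    if (length(bad) > 0L) {
      stop("row ", bad[1], ": missing or non-finite subscore '", col, "'")
    }
  }
  pin <- data.table::data.table(
    SpecId = sprintf("%s_%d_%d", x$source_file, x$light_scan, x$rank),
    Label = ifelse(x$is_decoy, -1L, 1L),
    ScanNr = x$light_scan,
    ld_score = x$ld_score
  )
  for (col in subs) pin[[col]] <- x[[col]]
  pin$rna_mass <- x$adduct_mass_da
  pin$rna_length <- vapply(x$rna_composition, function(tag) {
    if (is.na(tag) || tag == "") 0L else comp_length(parse_comp_tag(tag))
  }, integer(1), USE.NAMES = FALSE)
  pin$mass_error_ppm <- x$mass_error_ppm
  if ("charge" %in% names(x)) pin$charge <- x$charge
  pin$pep_len <- nchar(x$peptide)
  feat <- setdiff(names(pin), .PIN_FIXED)
  bad <- vapply(feat, function(col) any(!is.finite(pin[[col]])), logical(1))
  if (any(bad)) {
    stop("non-finite feature value(s) in: ",
         paste(feat[bad], collapse = ", "))
  }
  pin$Peptide <- sprintf("-.%s.-", x$peptide)
  pin$Proteins <- x$protein
  if (!is.null(path)) {
    data.table::fwrite(pin, path, sep = "\t")
    return(invisible(pin))
  }
  pin
}

#' Read a PIN file back into a table
#' @param path PIN path.
#' @return `data.table` in the layout [export_pin()] writes.
#' @export
read_pin <- function(path) {
  pin <- data.table::fread(path, sep = "\t")
  need <- c(.PIN_FIXED, "Peptide", "Proteins")
  miss <- setdiff(need, names(pin))
  if (length(miss) > 0L) {
    stop("PIN file missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(pin$Label %in% c(-1L, 1L))) stop("PIN Label must be +1/-1")
  pin
}

#' Write an FDR curve as TSV
#' @param curve An `fdr_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fdr_curve <- function(curve, path) {
  data.table::fwrite(data.table::as.data.table(curve), path, sep = "\t")
  invisible(path)
}
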