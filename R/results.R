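# Consolidation of cross-link spectrum matches (XLSMs): ingestion of
# per-search result tables, per-spectrum reranking, collapse to unique
# identifications, and mass-error window refinement.

.XLSM_MANDATORY <- c("source_file", "light_scan", "heavy_scan", "peptide",
                     "protein", "position", "rna_composition", "loss",
                     "adduct_mass_da", "ld_score", "mass_error_ppm")

#' Parse and consolidate per-search XLSM result tables
#'
#' Reads one TSV per parallel search in the documented dialect (columns
#' mirror the XLSM fields; any column prefixed `subscore_` is carried as a
#' search-engine subscore), assigns the decoy flag from the protein-id
#' prefix, and attaches the originating search group id.
#'
#' @param paths Character vector of TSV paths.
#' @param group_ids Optional search group id per path (recycled); default the
#'   file name without extension.
#' @param decoy_tag Protein-id prefix marking decoy records (default
#'   `"decoy_"`).
#' @return `data.table` of typed XLSM records with `is_decoy`,
#'   `search_group_id` and `rank = NA` columns appended.
#' @export
parse_search_results <- function(paths, group_ids = NULL,
                                 decoy_tag = "decoy_") {
  stopifnot(length(paths) >= 1L)
  if (is.null(group_ids)) {
    group_ids <- tools::file_path_sans_ext(basename(paths))
  }
  group_ids <- rep_len(group_ids, length(paths))
  tabs <- lapply(seq_along(paths), function(i) {
    dt <- tryCatch(data.table::fread(paths[i], sep = "\t"),
                   error = function(e) stop("cannot parse '", paths[i], "': ",
                                            conditionMessage(e)))
    miss <- setdiff(.XLSM_MANDATORY, names(dt))
    if (length(miss) > 0L) {
      stop("file '", paths[i], "' missing mandatory column(s): ",
           paste(miss, collapse = ", "))
    }
    bad <- which(!is.finite(dt$ld_score))
    if (length(bad) > 0L) {
      stop("file '", paths[i], "' row ", bad[1], ": non-finite ld_score")
    }
    if (any(dt$position < 1)) {
      stop("file '", paths[i], "' row ", which(dt$position < 1)[1],
           ": position must be >= 1")
    }
    dt$search_group_id <- group_ids[i]
    dt
  })
  x <- data.table::rbindlist(tabs, fill = TRUE)
  x$is_decoy <- startsWith(x$protein, decoy_tag)
  x$rank <- NA_integer_
  x[]
}

#' Subscore column names of an XLSM table
#' @param xlsm XLSM `data.table`.
#' @return Character vector of `subscore_*` columns.
#' @export
subscore_columns <- function(xlsm) {
  grep("^subscore_", names(xlsm), value = TRUE)
}

#' Rerank XLSMs so each spectrum yields at most one identification
#'
#' Parallel searches of the same data can assign one scan several competing
#' peptide-RNA explanations; downstream statistics require at most one per
#' spectrum. Within each spectrum key (source_file, light_scan, heavy_scan)
#' records are ordered by ld_score (descending), then shorter RNA
#' composition, then lexicographic composition tag, then target before
#' decoy, and assigned rank 1..n. Deterministic and independent of input
#' order.
#'
#' @param xlsm XLSM `data.table`.
#' @return The table with `rank` filled, ordered by spectrum key then rank.
#' @export
rerank_by_scan <- function(xlsm) {
  x <- data.table::as.data.table(xlsm)
  if (nrow(x) == 0L) {
    x$rank <- integer(0)
    return(x)
  }
  x$.rna_len <- vapply(x$rna_composition, function(tag) {
    if (is.na(tag) || tag == "") 0L else comp_length(parse_comp_tag(tag))
  }, integer(1), USE.NAMES = FALSE)
  data.table::setorder(x, source_file, light_scan, heavy_scan,
                       -ld_score, .rna_len, rna_composition, is_decoy,
                       protein, position, loss)
  x[, rank := seq_len(.N), by = c("source_file", "light_scan", "heavy_scan")]
  x$.rna_len <- NULL
  x[]
}

#' Keep only rank-1 records
#' @param xlsm Reranked XLSM table.
#' @return Rows with `rank == 1`.
#' @export
filter_rank1 <- function(xlsm) {
  if (any(is.na(xlsm$rank))) stop("table has not been reranked")
  xlsm[xlsm$rank == 1L]
}

#' Collapse rank-1 XLSMs to unique identifications
#'
#' An identification is a unique combination of the amino-acid position in
#' the protein and the cross-linked RNA product (composition + loss). The
#' highest-scoring representative is kept; `n_supporting_xlsms` counts the
#' collapsed records.
#'
#' @param xlsm Rank-1 XLSM table (see [filter_rank1()]).
#' @return `data.table`, one row per identification key (protein, position,
#'   rna_composition, loss), with all XLSM fields of the best record plus
#'   `n_supporting_xlsms`.
#' @export
collapse_to_unique_ids <- function(xlsm) {
  x <- data.table::as.data.table(xlsm)
  if (nrow(x) == 0L) return(x)
  if (any(x$rank != 1L)) stop("input must be rank-1 filtered")
  key <- c("protein", "position", "rna_composition", "loss")
  data.table::setorderv(x, c(key, "ld_score", "source_file", "light_scan"),
                        order = c(rep(1L, length(key)), -1L, 1L, 1L))
  x[, .n_sup := .N, by = key]
  out <- x[, .SD[1], by = key]
  data.table::setnames(out, ".n_sup", "n_supporting_xlsms")
  data.table::setorderv(out, key)
  out[]
}

#' Fit a mass-error acceptance window from target identifications
#'
#' Models the relative precursor mass errors (ppm) of target identifications
#' as a Gaussian via robust estimation — median center and 1.4826 x MAD
#' spread, refined by mean/sd of the values within 3 initial spreads of the
#' center — and defines the acceptance window `center +/- n_sigma * spread`.
#' The spread is floored at 0.1 ppm so a degenerate error cloud still yields
#' a usable window.
#'
#' @param targets XLSM or identification table; decoy rows are dropped.
#' @param n_sigma Window half-width in spreads (default 3).
#' @param min_n Minimum number of target records required (default 20).
#' @return Object of class `mass_error_model`: `center`, `spread`, `window`
#'   (low/high ppm), `n`, `residual`.
#' @export
fit_mass_error_tolerance <- function(targets, n_sigma = 3, min_n = 20L) {
  x <- data.table::as.data.table(targets)
  if ("is_decoy" %in% names(x)) x <- x[!x$is_decoy]
  err <- x$mass_error_ppm
  err <- err[is.finite(err)]
  if (length(err) < min_n) {
    stop("only ", length(err), " target records (< ", min_n,
         "); supply a manual mass-error window instead")
  }
  center0 <- stats::median(err)
  spread0 <- max(1.4826 * stats::mad(err, constant = 1), 0.1)
  inlier <- err[abs(err - center0) <= 3 * spread0]
  if (length(inlier) >= min_n) {
    center <- mean(inlier)
    spread <- max(stats::sd(inlier), 0.1)
  } else {
    center <- center0
    spread <- spread0
  }
  structure(list(
    center = center, spread = spread,
    window = c(low = center - n_sigma * spread,
               high = center + n_sigma * spread),
    n = length(err),
    residual = stats::sd(err - center)
  ), class = "mass_error_model")
}

#' @export
print.mass_error_model <- function(x, ...) {
  cat(sprintf(
    "<mass_error_model> center %.3f ppm, spread %.3f ppm, window [%.3f, %.3f] (n=%d)\n",
    x$center, x$spread, x$window["low"], x$window["high"], x$n))
  invisible(x)
}

#' Filter records by a fitted mass-error window
#' @param xlsm XLSM or identification table with `mass_error_ppm`.
#' @param model A `mass_error_model` from [fit_mass_error_tolerance()].
#' @return Rows whose mass error lies inside the window.
#' @export
filter_by_mass_error <- function(xlsm, model) {
  stopifnot(inherits(model, "mass_error_model"))
  xlsm[xlsm$mass_error_ppm >= model$window["low"] &
         xlsm$mass_error_ppm <= model$window["high"]]
}

#' Write a consolidated XLSM table as TSV
#' @param xlsm XLSM table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xlsm_table <- function(xlsm, path) {
  data.table::fwrite(xlsm, path, sep = "\t")
  invisible(path)
}
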