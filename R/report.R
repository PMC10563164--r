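# Protein-centric and RNA-centric reporting of filtered identifications.

#' Contingency of cross-link sites by RNA product
#'
#' Protein-centric view: which RNA products were detected at each amino-acid
#' position. Cells hold identification counts (`mode = "count"`) or the best
#' ld-score (`mode = "best_score"`).
#'
#' @param ids Filtered unique identifications (one row per identification).
#' @param mode `"count"` or `"best_score"`.
#' @return Object of class `site_adduct_matrix`: a `data.table` in long form
#'   (protein, position, rna_product, value) sorted by protein, position,
#'   product, plus a `wide` matrix attribute (sites x products).
#' @export
site_adduct_counts <- function(ids, mode = c("count", "best_score")) {
  mode <- match.arg(mode)
  x <- data.table::as.data.table(ids)
  if (nrow(x) > 0L) {
    key <- c("protein", "position", "rna_composition", "loss")
    if (anyDuplicated(x, by = key) > 0L) {
      stop("input is not unique at the identification level; collapse first")
    }
  }
  prod_tag <- function(comp, loss) {
    ifelse(is.na(loss) | loss == "none" | loss == "", comp,
           paste0(comp, loss))
  }
  if (nrow(x) == 0L) {
    long <- data.table::data.table(protein = character(),
                                   position = integer(),
                                   rna_product = character(),
                                   value = numeric())
    wide <- matrix(numeric(0), nrow = 0, ncol = 0)
  } else {
    x$rna_product <- prod_tag(x$rna_composition, x$loss)
    long <- x[, if (mode == "count") list(value = as.numeric(.N)) else
      list(value = max(ld_score)),
      by = c("protein", "position", "rna_product")]
    data.table::setorder(long, protein, position, rna_product)
    sites <- unique(long[, c("protein", "position")])
    site_lab <- sprintf("%s:%d", sites$protein, sites$position)
    prods <- sort(unique(long$rna_product))
    wide <- matrix(0, nrow = nrow(sites), ncol = length(prods),
                   dimnames = list(site_lab, prods))
    lab <- sprintf("%s:%d", long$protein, long$position)
    wide[cbind(lab, long$rna_product)] <- long$value
  }
  structure(long, wide = wide, mode = mode,
            class = c("site_adduct_matrix", class(long)))
}

#' Positional interaction profile over the input RNA
#'
#' RNA-centric view: each identification's RNA composition is matched against
#' all contiguous windows of the input RNA with the same base composition;
#' weight is split equally over compatible windows and accumulated onto the
#' nucleotide positions each window covers. With `normalize = TRUE` the
#' weight is further divided by the adduct length so every matched
#' identification contributes total weight 1 (a probabilistic placement);
#' otherwise each covered position receives the full window share, as in a
#' coverage plot. Identifications whose composition matches no window are
#' listed in `unmatched`, never silently dropped.
#'
#' @param ids Filtered unique identifications with `rna_composition`.
#' @param rna_sequence The RNA the sample was prepared with (A/C/G/U).
#' @param normalize Logical; see above. Default `FALSE`.
#' @return Object of class `rna_position_profile`: list with `weights`
#'   (numeric, one per nucleotide, named by base), `unmatched` (data.table of
#'   non-matching identifications), `n_ids`, `normalized`.
#' @export
rna_position_profile <- function(ids, rna_sequence, normalize = FALSE) {
  chars <- .check_rna_sequence(rna_sequence)
  n <- length(chars)
  x <- data.table::as.data.table(ids)
  w <- setNames(numeric(n), chars)
  unmatched_idx <- integer(0)
  for (i in seq_len(nrow(x))) {
    tag <- x$rna_composition[i]
    if (is.na(tag) || tag == "") {
      unmatched_idx <- c(unmatched_idx, i)
      next
    }
    comp <- parse_comp_tag(tag)
    k <- comp_length(comp)
    wins <- integer(0)
    if (k <= n) {
      target <- unclass(comp)
      for (s in seq_len(n - k + 1L)) {
        v <- setNames(integer(4), .RNA_BASES)
        for (b in chars[s:(s + k - 1L)]) v[b] <- v[b] + 1L
        if (all(v == target)) wins <- c(wins, s)
      }
    }
    if (length(wins) == 0L) {
      unmatched_idx <- c(unmatched_idx, i)
      next
    }
    share <- 1 / length(wins)
    if (normalize) share <- share / k
    for (s in wins) {
      idx <- s:(s + k - 1L)
      w[idx] <- w[idx] + share
    }
  }
  structure(list(
    weights = w,
    unmatched = x[unmatched_idx],
    n_ids = nrow(x),
    normalized = normalize
  ), class = "rna_position_profile")
}

#' @export
print.rna_position_profile <- function(x, ...) {
  cat("<rna_position_profile>", length(x$weights), "nt,",
      x$n_ids, "identifications,", nrow(x$unmatched), "unmatched",
      if (x$normalized) "(normalized)" else "", "\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' Write the minimum-information summary CSV
#'
#' One row per filtered identification with the fields a structural-modeling
#' pipeline needs: protein, position, peptide, rna_composition, loss,
#' adduct_mass_da, ld_score, q_value, n_supporting_xlsms. RFC-4180 quoting;
#' the header is always written.
#'
#' @param ids Filtered unique identifications; `q_value` and
#'   `n_supporting_xlsms` are filled with NA / 1 when absent.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(ids, path) {
  x <- data.table::as.data.table(ids)
  cols <- c("protein", "position", "peptide", "rna_composition", "loss",
            "adduct_mass_da", "ld_score", "q_value", "n_supporting_xlsms")
  if (!"q_value" %in% names(x)) x$q_value <- rep(NA_real_, nrow(x))
  if (!"n_supporting_xlsms" %in% names(x)) {
    x$n_supporting_xlsms <- rep(1L, nrow(x))
  }
  miss <- setdiff(cols, names(x))
  if (length(miss) > 0L) {
    stop("identification table missing column(s): ",
         paste(miss, collapse = ", "))
  }
  out <- x[, cols, with = FALSE]
  data.table::fwrite(out, path, sep = ",", quote = TRUE, na = "")
  invisible(path)
}
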