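# Independent brute-force oracles. These deliberately re-derive expected
# values by the most naive route available and stay independent of the
# package code paths they check.

# --- composition enumeration: naive substring + multiset dedup -------------
oracle_compositions <- function(rna, min_len, max_len) {
  chars <- strsplit(toupper(rna), "")[[1]]
  tags <- character(0)
  for (k in min_len:max_len) {
    if (k > length(chars)) next
    for (i in seq_len(length(chars) - k + 1L)) {
      cnt <- table(factor(chars[i:(i + k - 1L)], levels = c("A", "C", "G", "U")))
      tags <- c(tags, paste0(names(cnt)[cnt > 0], cnt[cnt > 0], collapse = ""))
    }
  }
  sort(unique(tags))
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# --- monoisotopic mass summation: own constants, plain arithmetic ----------
ORACLE_ATOM <- c(H = 1.007825032, C = 12.0, N = 14.003074005,
                 O = 15.994914620, P = 30.973761998)
ORACLE_D13C <- 1.0033548
ORACLE_D15N <- 0.9970349

ORACLE_NMP <- list(  # nucleoside-5'-monophosphates, free acid
  A = c(C = 10, H = 14, N = 5, O = 7, P = 1),
  C = c(C = 9, H = 14, N = 3, O = 8, P = 1),
  G = c(C = 10, H = 14, N = 5, O = 8, P = 1),
  U = c(C = 9, H = 13, N = 2, O = 9, P = 1)
)

oracle_sum_mass <- function(counts) {
  s <- 0
  for (el in names(counts)) s <- s + counts[[el]] * ORACLE_ATOM[[el]]
  s
}

# light mass of an oligo adduct: sum of NMPs minus (n-1) waters minus loss
oracle_adduct_mass <- function(base_counts, loss_counts = NULL) {
  total <- c(C = 0, H = 0, N = 0, O = 0, P = 0)
  n <- 0
  for (b in names(base_counts)) {
    k <- base_counts[[b]]
    n <- n + k
    total <- total + k * c(ORACLE_NMP[[b]], recursive = TRUE)[names(total)]
  }
  total["H"] <- total["H"] - 2 * (n - 1)
  total["O"] <- total["O"] - (n - 1)
  if (!is.null(loss_counts)) {
    for (el in names(loss_counts)) total[el] <- total[el] - loss_counts[[el]]
  }
  oracle_sum_mass(as.list(total))
}

# --- observed FDR: exhaustive recount at every threshold -------------------
oracle_fdr_curve <- function(scores, is_decoy) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_t <- vapply(thr, function(t) sum(scores >= t & !is_decoy), numeric(1))
  n_d <- vapply(thr, function(t) sum(scores >= t & is_decoy), numeric(1))
  fdr <- ifelse(n_t == 0, 1, pmin(n_d / n_t, 1))
  # q(t): minimum FDR over all thresholds at or below t
  q <- vapply(seq_along(thr), function(i) min(fdr[i:length(fdr)]), numeric(1))
  data.frame(score = thr, n_target = n_t, n_decoy = n_d, fdr = fdr,
             q_value = q)
}

random_score_table <- function(n) {
  list(scores = round(stats::runif(n, 0, 50), 3),
       is_decoy = stats::runif(n) < 0.4)
}

with_seed_sample <- function(dt, seed) {
  set.seed(seed)
  dt[sample(nrow(dt))]
}

# small consolidated XLSM table built by hand for results-module tests
make_xlsm_rows <- function(ld, comp, scan = 1L, protein = "SP1",
                           position = 10L, loss = "none",
                           decoy = FALSE, file = "f.mzXML") {
  n <- length(ld)
  data.table::data.table(
    source_file = file, light_scan = rep_len(scan, n),
    heavy_scan = rep_len(scan, n) + 1L,
    peptide = "PEPTIDEK", protein = rep_len(protein, n),
    position = rep_len(position, n),
    rna_composition = rep_len(comp, n), loss = rep_len(loss, n),
    adduct_mass_da = 324.0359, ld_score = ld,
    mass_error_ppm = 1.0, charge = 2L,
    search_group_id = "g1", is_decoy = rep_len(decoy, n),
    rank = NA_integer_,
    subscore_xcorrb = 0.03 * ld, subscore_xcorrx = 0.04 * ld,
    subscore_match_odds = 0.5 * ld, subscore_intsum = 0.1 * ld
  )
}
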