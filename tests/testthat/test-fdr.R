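# Observed FDR with q-values, thresholding, transferred FDR, PIN export.

worked_example <- function() {
  list(scores = c(30, 28, 25, 20, 18, 15, 19, 14),
       is_decoy = c(rep(FALSE, 6), rep(TRUE, 2)))
}

test_that("observed FDR reproduces the worked curve", {
  w <- worked_example()
  curve <- observed_fdr(w$scores, w$is_decoy)
  at <- function(s) curve[curve$score == s, ]
  expect_equal(at(20)$fdr, 0)
  expect_equal(at(20)$n_target, 4)
  expect_equal(at(15)$fdr, 1 / 6)
  expect_equal(at(15)$q_value, 1 / 6)
  expect_equal(at(19)$fdr, 1 / 4)
  expect_equal(at(19)$q_value, 1 / 6)  # rescued by the lower threshold

  # no decoys: FDR and q identically zero
  c0 <- observed_fdr(c(5, 8, 2), rep(FALSE, 3))
  expect_true(all(c0$fdr == 0) && all(c0$q_value == 0))

  # all decoys above all targets: q = 1 wherever targets exist
  c1 <- observed_fdr(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_true(all(c1$q_value[c1$score <= 3] == 1))

  expect_error(observed_fdr(numeric(0), logical(0)), "empty")
})

test_that("thresholding picks the lowest qualifying target score", {
  w <- worked_example()
  ids <- data.table::data.table(ld_score = w$scores, is_decoy = w$is_decoy)
  curve <- observed_fdr(w$scores, w$is_decoy)

  thr <- apply_fdr_threshold(curve, ids, alpha = 0.01)
  expect_equal(thr$cutoff, 20)
  expect_equal(nrow(thr$ids), 4)
  expect_identical(thr$status, "ok")

  thr2 <- apply_fdr_threshold(curve, ids, alpha = 0.5)
  expect_equal(thr2$cutoff, 15)
  expect_equal(nrow(thr2$ids), 6)

  # nothing passes when min q exceeds alpha
  ids3 <- data.table::data.table(ld_score = c(10, 9, 11, 12, 13),
                                 is_decoy = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  c3 <- observed_fdr(ids3$ld_score, ids3$is_decoy)
  thr3 <- apply_fdr_threshold(c3, ids3, alpha = 0.01)
  expect_identical(thr3$status, "nothing passes")
  expect_equal(nrow(thr3$ids), 0)
})

test_that("observed FDR equals the brute-force oracle on random tables", {
  set.seed(41)
  for (i in 1:50) {
    tab <- random_score_table(sample(5:300, 1))
    if (!any(!tab$is_decoy)) next
    curve <- observed_fdr(tab$scores, tab$is_decoy)
    oracle <- oracle_fdr_curve(tab$scores, tab$is_decoy)
    expect_identical(curve$score, oracle$score)
    expect_equal(curve$n_target, oracle$n_target)
    expect_equal(curve$n_decoy, oracle$n_decoy)
    expect_equal(curve$fdr, oracle$fdr)
    expect_equal(curve$q_value, oracle$q_value)
    # q monotone non-increasing with score
    expect_true(all(diff(curve$q_value) >= 0))  # scores are descending
  }
})

test_that("transferred FDR reduces to observed FDR for a single bin", {
  set.seed(42)
  cfg <- synthetic_config(seed = 42, n_true_targets = 300L,
                          n_chance_targets = 150L, n_decoys = 150L)
  u <- collapse_to_unique_ids(filter_rank1(rerank_by_scan(
    simulate_xlsm_table(cfg))))
  u$one_bin <- "all"
  bt <- transferred_fdr(u, bin_col = "one_bin")
  expect_equal(nrow(bt), 1)
  expect_identical(bt$method, "transferred")
  expect_equal(bt$pi, 1, tolerance = 1e-9)
  glob <- apply_fdr_threshold(observed_fdr(u$ld_score, u$is_decoy), u, 0.01)
  expect_equal(bt$cutoff, glob$cutoff)
})

test_that("zero-decoy bins always resolve via the observed fallback", {
  ids <- data.table::data.table(
    ld_score = c(rnorm(200, 30, 3), rnorm(100, 15, 3), rnorm(100, 15, 3)),
    is_decoy = c(rep(FALSE, 300), rep(TRUE, 100)),
    rna_composition = "U1")
  ids$rna_composition[1:20] <- "G1"   # all targets, no decoys
  bt <- transferred_fdr(ids)
  g1 <- bt[bt$bin == "G1", ]
  expect_identical(g1$method, "fallback_observed")
  glob <- apply_fdr_threshold(observed_fdr(ids$ld_score, ids$is_decoy),
                              ids, 0.01)
  expect_equal(g1$cutoff, glob$cutoff)
  # totality: every bin got a finite or Inf cutoff, none errored
  expect_setequal(bt$bin, unique(ids$rna_composition))
  expect_false(any(is.na(bt$cutoff)))
})

test_that("transferred FDR recovers a bin's decoy share", {
  set.seed(43)
  pis <- replicate(20, {
    n <- 500
    dec_scores <- rnorm(2 * n, 18, 3.5)
    ids <- data.table::data.table(
      ld_score = c(rnorm(800, 30, 3), rnorm(800, 30, 3), dec_scores),
      is_decoy = c(rep(FALSE, 1600), rep(TRUE, 2 * n)),
      rna_composition = c(rep("U1", 800), rep("C1U1", 800),
                          rep(c("U1", "C1U1"), n)))
    bt <- transferred_fdr(ids)
    bt$pi[bt$bin == "U1"]
  })
  expect_lt(abs(mean(pis) - 0.5), 0.1)
  expect_true(all(abs(pis - 0.5) < 0.1))
})

test_that("PIN export satisfies the Percolator contract and round-trips", {
  x <- rbind(make_xlsm_rows(25, "U1", scan = 5L),
             make_xlsm_rows(18, "C1U1", scan = 9L, decoy = TRUE,
                            protein = "decoy_SP1"))
  x <- rerank_by_scan(x)
  path <- tempfile(fileext = ".pin")
  on.exit(unlink(path))
  export_pin(x, path)

  lines <- readLines(path)
  expect_length(lines, 3)  # header + 2 rows
  pin <- read_pin(path)
  expect_identical(names(pin)[1:3], c("SpecId", "Label", "ScanNr"))
  expect_identical(tail(names(pin), 2), c("Peptide", "Proteins"))
  expect_setequal(pin$Label, c(1L, -1L))
  expect_identical(pin$ScanNr, c(5L, 9L))
  # the calculated peptide mass addition is exported as rna_mass
  expect_equal(pin$rna_mass, x$adduct_mass_da)
  expect_true(all(grepl("^-\\..*\\.-$", pin$Peptide)))

  # round-trip equals the in-memory table
  expect_equal(as.data.frame(read_pin(path)), as.data.frame(export_pin(x)),
               tolerance = 1e-12)

  # missing subscore is an error naming the row
  x2 <- data.table::copy(x)
  x2$subscore_xcorrb[2] <- NA_real_
  expect_error(export_pin(x2), "row 2")
})
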