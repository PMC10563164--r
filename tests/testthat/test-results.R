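# Result consolidation, reranking, unique-ID collapse, mass-error window.

write_dialect_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t")
  path
}

test_that("parse_search_results consolidates files and assigns decoy flags", {
  d1 <- make_xlsm_rows(c(25, 18, 12), "U1", scan = c(1L, 2L, 3L))
  d2 <- make_xlsm_rows(c(30, 22, 9), "C1U1", scan = c(4L, 5L, 6L),
                       protein = "decoy_FOX1")
  d1$is_decoy <- d1$rank <- NULL
  d2$is_decoy <- d2$rank <- NULL
  p1 <- write_dialect_tsv(d1, tempfile(fileext = ".tsv"))
  p2 <- write_dialect_tsv(d2, tempfile(fileext = ".tsv"))
  on.exit(unlink(c(p1, p2)))

  x <- parse_search_results(c(p1, p2), group_ids = c("g1", "g2"))
  expect_equal(nrow(x), 6)
  expect_identical(x$is_decoy, rep(c(FALSE, TRUE), each = 3))
  expect_setequal(unique(x$search_group_id), c("g1", "g2"))

  # missing mandatory column is named in the error
  d3 <- data.table::copy(d1)
  d3$ld_score <- NULL
  p3 <- write_dialect_tsv(d3, tempfile(fileext = ".tsv"))
  on.exit(unlink(p3), add = TRUE)
  expect_error(parse_search_results(p3), "ld_score")
})

test_that("rerank orders within each spectrum by the documented tie-breaks", {
  # score decides first
  x <- make_xlsm_rows(c(18.3, 25.1), "U1", scan = 1042L)
  r <- rerank_by_scan(x)
  expect_identical(r$rank[r$ld_score == 25.1], 1L)
  expect_identical(r$rank[r$ld_score == 18.3], 2L)
  expect_equal(nrow(filter_rank1(r)), 1)
  expect_equal(filter_rank1(r)$ld_score, 25.1)

  # tie on score: shorter RNA composition wins
  x2 <- rbind(make_xlsm_rows(20.0, "C1U1", scan = 7L),
              make_xlsm_rows(20.0, "U1", scan = 7L))
  r2 <- rerank_by_scan(x2)
  expect_identical(r2$rna_composition[r2$rank == 1L], "U1")

  # tie on score and length: target beats decoy
  x3 <- rbind(make_xlsm_rows(20.0, "U1", scan = 8L, decoy = TRUE,
                             protein = "decoy_SP1"),
              make_xlsm_rows(20.0, "U1", scan = 8L))
  r3 <- rerank_by_scan(x3)
  expect_false(r3$is_decoy[r3$rank == 1L])

  # single record keeps rank 1
  expect_identical(rerank_by_scan(make_xlsm_rows(10, "U1"))$rank, 1L)
})

test_that("rerank is idempotent, permutation-invariant, one-per-scan", {
  set.seed(31)
  cfg <- synthetic_config(seed = 31, n_true_targets = 120L,
                          n_chance_targets = 60L, n_decoys = 60L,
                          dup_scan_frac = 0.3)
  x <- simulate_xlsm_table(cfg)
  r1 <- rerank_by_scan(x)
  expect_identical(rerank_by_scan(r1), r1)
  r2 <- rerank_by_scan(x[sample(nrow(x))])
  expect_identical(r2, r1)
  keys <- filter_rank1(r1)[, paste(source_file, light_scan, heavy_scan)]
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("collapse keeps the best record per identification key", {
  a <- make_xlsm_rows(30, "U1", scan = 1L)
  b <- make_xlsm_rows(22, "U1", scan = 2L)     # same site + product
  c_ <- make_xlsm_rows(15, "C1U1", scan = 3L)  # same site, other product
  x <- rerank_by_scan(rbind(a, b, c_))
  u <- collapse_to_unique_ids(filter_rank1(x))
  expect_equal(nrow(u), 2)
  expect_equal(u[u$rna_composition == "U1", ]$ld_score, 30)
  expect_equal(u[u$rna_composition == "U1", ]$n_supporting_xlsms, 2L)

  # collapse dominance on simulated data
  cfg <- synthetic_config(seed = 32, n_true_targets = 150L,
                          n_chance_targets = 80L, n_decoys = 80L)
  r1 <- filter_rank1(rerank_by_scan(simulate_xlsm_table(cfg)))
  u2 <- collapse_to_unique_ids(r1)
  expect_lte(nrow(u2), nrow(r1))
  key <- paste(r1$protein, r1$position, r1$rna_composition, r1$loss)
  ukey <- paste(u2$protein, u2$position, u2$rna_composition, u2$loss)
  best <- tapply(r1$ld_score, key, max)
  expect_equal(u2$ld_score, as.numeric(best[ukey]))

  # empty input collapses to empty
  expect_equal(nrow(collapse_to_unique_ids(r1[0])), 0)
})

test_that("mass-error model recovers simulated Gaussian parameters", {
  set.seed(33)
  x <- make_xlsm_rows(rnorm(1000, 25, 3), "U1", scan = seq_len(1000))
  x$mass_error_ppm <- rnorm(1000, 1.5, 1.0)
  m <- fit_mass_error_tolerance(x)
  expect_lt(abs(m$center - 1.5), 0.2)
  expect_lt(abs(m$spread - 1.0), 0.2)
  expect_true(m$window["low"] < m$center && m$center < m$window["high"])
})

test_that("mass-error window handles degenerate and outlier cases", {
  x <- make_xlsm_rows(rep(20, 30), "U1", scan = 1:30)
  x$mass_error_ppm <- rep(2.0, 30)
  m <- fit_mass_error_tolerance(x)
  expect_gte(m$spread, 0.1)  # floored
  expect_true(m$window["low"] <= 2.0 && 2.0 <= m$window["high"])

  # crafted outliers are exactly the removed records
  x2 <- make_xlsm_rows(rep(20, 52), "U1", scan = 1:52)
  x2$mass_error_ppm <- c(rnorm(50, 1.5, 0.5), -20, 20)
  m2 <- fit_mass_error_tolerance(x2)
  kept <- filter_by_mass_error(x2, m2)
  expect_equal(nrow(kept), 50)
  expect_true(all(abs(kept$mass_error_ppm) < 19))

  # too few targets instructs a manual window
  expect_error(fit_mass_error_tolerance(x2[1:5]), "manual")
  # decoys are excluded from the fit
  x3 <- rbind(x2, make_xlsm_rows(rep(10, 5), "U1", scan = 60:64,
                                 decoy = TRUE, protein = "decoy_SP1"))
  m3 <- fit_mass_error_tolerance(x3)
  expect_identical(m3$n, 52L)
})
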