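# Synthetic-data generator. Emulates the statistical structure of isotope-
# labeled protein-RNA cross-linking searches so every pipeline stage can be
# exercised without raw data: bimodal target ld-score distributions whose
# high mode shifts lower with RNA adduct length, a unimodal low decoy/chance
# distribution independent of length, Gaussian ppm mass errors, and
# precursor runs containing light/heavy scan pairs at expected delta masses.

#' Synthetic experiment configuration
#'
#' Defaults describe a small single-protein experiment with a short labeled
#' RNA (FOX1-like, `UGCAUGU`): roughly two thirds of target matches are
#' correct, high-mode ld-scores centered at 34 for mononucleotide adducts
#' dropping 2 score units per additional nucleotide, and chance/decoy
#' matches from a shared low mode at 18. Mass errors are Normal(1.5, 1.0)
#' ppm. See the methods vignette for the rationale behind each value.
#'
#' @param seed Integer seed; identical config + seed gives identical output.
#' @param rna_sequence Labeled RNA (A/C/G/U).
#' @param scheme A [labeling_scheme()]; default metabolic 13C/15N.
#' @param max_len Maximum adduct length sampled (default 4).
#' @param n_true_targets,n_chance_targets,n_decoys Record counts.
#' @param true_mean_base High-mode ld-score mean for length-1 adducts.
#' @param true_len_slope Score-mean decrease per extra nucleotide.
#' @param true_sd High-mode standard deviation.
#' @param null_mean,null_sd Low-mode (chance/decoy) score parameters.
#' @param mass_error_mean,mass_error_sd Target mass-error distribution, ppm.
#' @param dup_scan_frac Fraction of spectra given a competing lower-ranked
#'   candidate, to exercise reranking.
#' @param n_pairs,n_background Precursor-run composition (injected
#'   light/heavy pairs and unpaired background precursors).
#' @param pair_ppm_jitter Max |ppm| error injected into pair delta masses.
#' @param pair_rt_jitter_s Max |RT gap| in seconds for injected pairs.
#' @param control_run If TRUE: no true targets and no injected pairs (a
#'   no-UV control).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             rna_sequence = "UGCAUGU",
                             scheme = labeling_scheme("metabolic_13C15N"),
                             max_len = 4L,
                             n_true_targets = 900L,
                             n_chance_targets = 550L,
                             n_decoys = 550L,
                             true_mean_base = 34,
                             true_len_slope = 2,
                             true_sd = 3,
                             null_mean = 18,
                             null_sd = 3.5,
                             mass_error_mean = 1.5,
                             mass_error_sd = 1.0,
                             dup_scan_frac = 0.05,
                             n_pairs = 25L,
                             n_background = 50L,
                             pair_ppm_jitter = 3,
                             pair_rt_jitter_s = 20,
                             control_run = FALSE) {
  .check_rna_sequence(rna_sequence)
  stopifnot(n_true_targets >= 0, n_chance_targets >= 0, n_decoys >= 0,
            true_sd > 0, null_sd > 0, mass_error_sd > 0,
            inherits(scheme, "labeling_scheme"))
  if (control_run) {
    n_true_targets <- 0L
    n_pairs <- 0L
  }
  structure(as.list(environment()), class = "synthetic_config")
}

# adduct species lookup for a config: composition tag -> light mass, delta,
# length; loss "none" only (losses enter via the results dialect, not the
# score model)
.cfg_species <- function(cfg) {
  comps <- enumerate_compositions(cfg$rna_sequence, 1L,
                                  min(cfg$max_len, nchar(cfg$rna_sequence)))
  sp <- lapply(comps, function(cm)
    build_adduct_species(cm, scheme = cfg$scheme))
  data.table::data.table(
    composition = vapply(sp, function(s) comp_tag(s$composition), character(1)),
    length = vapply(sp, function(s) comp_length(s$composition), integer(1)),
    light_mass_da = vapply(sp, function(s) s$light_mass_da, numeric(1)),
    delta_mass_da = vapply(sp, function(s) s$delta_mass_da, numeric(1))
  )
}

.rand_peptide <- function(n) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aas, sample(8:15, 1), replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a consolidated XLSM table with ground truth
#'
#' Generates target and decoy cross-link spectrum matches in the dialect
#' [parse_search_results()] reads. True targets draw ld-scores from the high
#' mode (mean decreasing with RNA length); chance targets and decoys draw
#' from the shared low mode, making the decoy distribution a valid model of
#' false targets for target-decoy FDR. Subscores are noisy monotone
#' transforms of the ld-score. Each record carries a hidden `is_true` flag
#' for false-discovery-proportion evaluation; a fraction of spectra receive
#' a second, lower-scoring candidate to exercise reranking.
#'
#' @param cfg A [synthetic_config()].
#' @return `data.table` of XLSM records (mandatory dialect columns, four
#'   `subscore_*` columns, `charge`, `search_group_id`, `is_decoy`, `rank =
#'   NA`) plus the ground-truth column `is_true`.
#' @export
simulate_xlsm_table <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  species <- .cfg_species(cfg)
  with_local_seed(cfg$seed, {
    n_t <- cfg$n_true_targets
    n_c <- cfg$n_chance_targets
    n_d <- cfg$n_decoys
    n <- n_t + n_c + n_d
    if (n == 0L) stop("config generates no records")

    # adduct species per record; shorter adducts more likely
    wt <- 0.6^(species$length - 1)
    sp_idx <- sample(nrow(species), n, replace = TRUE, prob = wt)
    len <- species$length[sp_idx]

    kind <- rep(c("true", "chance", "decoy"), c(n_t, n_c, n_d))
    ld <- numeric(n)
    is_true <- kind == "true"
    ld[is_true] <- stats::rnorm(sum(is_true),
      cfg$true_mean_base - cfg$true_len_slope * (len[is_true] - 1),
      cfg$true_sd)
    ld[!is_true] <- stats::rnorm(sum(!is_true), cfg$null_mean, cfg$null_sd)

    is_decoy <- kind == "decoy"
    protein <- ifelse(is_decoy,
                      sample(c("decoy_SP1", "decoy_SP2"), n, replace = TRUE),
                      sample(c("SP1", "SP2"), n, replace = TRUE))
    pep <- .rand_peptide(n)
    light_scan <- 1000L + 2L * seq_len(n)

    dt <- data.table::data.table(
      source_file = "sim_run.mzXML",
      light_scan = light_scan,
      heavy_scan = light_scan + 1L,
      peptide = pep,
      protein = protein,
      position = sample(400L, n, replace = TRUE),
      rna_composition = species$composition[sp_idx],
      loss = "none",
      adduct_mass_da = species$light_mass_da[sp_idx],
      ld_score = ld,
      mass_error_ppm = stats::rnorm(n, cfg$mass_error_mean,
                                    cfg$mass_error_sd),
      charge = sample(2:3, n, replace = TRUE),
      search_group_id = sprintf("sim_%s", species$composition[sp_idx]),
      is_decoy = is_decoy,
      is_true = is_true
    )

    # competing lower-scored candidates on a fraction of spectra
    n_dup <- round(cfg$dup_scan_frac * n)
    if (n_dup > 0L) {
      dup <- dt[sample(n, n_dup)]
      alt_idx <- sample(nrow(species), n_dup, replace = TRUE)
      dup$rna_composition <- species$composition[alt_idx]
      dup$adduct_mass_da <- species$light_mass_da[alt_idx]
      dup$search_group_id <- sprintf("sim_%s", dup$rna_composition)
      dup$ld_score <- dup$ld_score - stats::runif(n_dup, 0.5, 5)
      dup$is_true <- FALSE
      dt <- data.table::rbindlist(list(dt, dup))
    }

    # subscores: noisy monotone transforms of the ld-score
    m <- nrow(dt)
    dt$subscore_xcorrb <- 0.03 * dt$ld_score + stats::rnorm(m, 0, 0.05)
    dt$subscore_xcorrx <- 0.04 * dt$ld_score + stats::rnorm(m, 0, 0.05)
    dt$subscore_match_odds <- 0.5 * dt$ld_score + stats::rnorm(m, 0, 1)
    dt$subscore_intsum <- 0.1 * dt$ld_score + stats::rnorm(m, 0, 0.2)
    dt$rank <- NA_integer_
    data.table::setorder(dt, light_scan, -ld_score)
    dt[]
  })
}

#' Simulate a precursor-level mzXML run with injected isotope pairs
#'
#' Writes an mzXML file containing MS1 scans, `n_pairs` injected light/heavy
#' MS2 precursor pairs at the labeling scheme's delta masses (ppm and RT
#' jitter within the configured bounds), and `n_background` unpaired
#' precursors rejection-sampled to sit at least twice the matching tolerance
#' away from any valid pair offset. A control run injects no pairs.
#'
#' @param cfg A [synthetic_config()].
#' @param path Output mzXML path.
#' @param ppm_tol,rt_tol_s The matching tolerances the background must avoid
#'   (defaults 10 ppm / 60 s, as used by [find_isotope_pairs()]).
#' @return List: `path`, `ledger` (data.table of injected pairs: light_scan,
#'   heavy_scan, delta_da, charge), `deltas` (expected delta masses).
#' @export
simulate_precursor_run <- function(cfg, path, ppm_tol = 10, rt_tol_s = 60) {
  stopifnot(inherits(cfg, "synthetic_config"))
  species <- .cfg_species(cfg)
  deltas <- sort(unique(round(species$delta_mass_da, 6)))
  with_local_seed(cfg$seed + 7L, {
    # every new precursor must sit at least twice the matching tolerance
    # away from any valid pair offset relative to the records placed so far,
    # so the only recoverable pairs are the intended ones
    off_ok <- function(mz, z, cur) {
      others <- cur[cur$charge == z]
      if (nrow(others) == 0L) return(TRUE)
      for (om in others$mz) {
        gap <- abs(mz - om)
        for (delta in deltas) {
          tol_mz <- ppm_tol * 1e-6 * max(mz, om)
          if (abs(gap - delta / z) < 2 * tol_mz) return(FALSE)
        }
      }
      TRUE
    }
    cur <- data.table::data.table(mz = numeric(), charge = integer(),
                                  rt = numeric(), tag = character())
    for (i in seq_len(cfg$n_pairs)) {
      repeat {
        z <- sample(2:3, 1)
        mz <- stats::runif(1, 400, 900)
        delta <- deltas[sample.int(length(deltas), 1)]
        jit_ppm <- stats::runif(1, -cfg$pair_ppm_jitter, cfg$pair_ppm_jitter)
        heavy_mz <- mz + delta / z + jit_ppm * 1e-6 * mz
        if (off_ok(mz, z, cur) && off_ok(heavy_mz, z, cur)) break
      }
      rt <- stats::runif(1, 120, 2800)
      heavy_rt <- max(rt + stats::runif(1, -cfg$pair_rt_jitter_s,
                                        cfg$pair_rt_jitter_s), 0)
      cur <- data.table::rbindlist(list(cur, data.table::data.table(
        mz = c(mz, heavy_mz), charge = z, rt = c(rt, heavy_rt),
        tag = sprintf(c("pairL_%d_%.6f", "pairH_%d_%.6f"), i, delta))))
    }
    for (i in seq_len(cfg$n_background)) {
      repeat {
        z <- sample(2:3, 1)
        mz <- stats::runif(1, 400, 950)
        if (off_ok(mz, z, cur)) break
      }
      rt <- stats::runif(1, 60, 2900)
      cur <- data.table::rbindlist(list(cur, data.table::data.table(
        mz = mz, charge = z, rt = rt, tag = sprintf("bg_%d", i))))
    }

    data.table::setorder(cur, rt)
    cur$scan <- seq_len(nrow(cur)) * 2L  # leave room for MS1 scans
    scans <- list()
    for (i in seq_len(nrow(cur))) {
      if (i %% 10L == 1L) {
        scans[[length(scans) + 1L]] <- list(
          num = cur$scan[i] - 1L, ms_level = 1L, rt_s = max(cur$rt[i] - 1, 0),
          mz = seq(400, 1200, by = 200),
          intensity = rep(1e4, 5))
      }
      frag_mz <- sort(stats::runif(5, 150, cur$mz[i] * cur$charge[i]))
      scans[[length(scans) + 1L]] <- list(
        num = cur$scan[i], ms_level = 2L, rt_s = cur$rt[i],
        precursor_mz = cur$mz[i], precursor_charge = cur$charge[i],
        mz = frag_mz, intensity = stats::runif(5, 1e3, 1e5))
    }
    write_mzxml(scans, path)

    is_l <- startsWith(cur$tag, "pairL_")
    ledger <- if (any(is_l)) {
      key <- sub("^pairL_", "", cur$tag[is_l])
      heavy <- cur[match(paste0("pairH_", key), cur$tag)]
      data.table::data.table(
        light_scan = cur$scan[is_l],
        heavy_scan = heavy$scan,
        delta_da = as.numeric(sub("^[0-9]+_", "", key)),
        charge = cur$charge[is_l])
    } else {
      data.table::data.table(light_scan = integer(), heavy_scan = integer(),
                             delta_da = numeric(), charge = integer())
    }
    list(path = path, ledger = ledger, deltas = deltas)
  })
}
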