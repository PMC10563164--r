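# Search orchestration: per-group parameter file sets, a light-only search
# definition, decoy protein databases, and the execution manifest.

#' Search configuration
#'
#' Bundles everything a parallel-search run needs. Defaults follow common
#' practice for tryptic digests on high-resolution instruments: trypsin, two
#' missed cleavages, 10 ppm precursor tolerance, 0.2 / 0.3 Da fragment
#' tolerances for common and cross-link ions.
#'
#' @param fasta Character vector of protein FASTA path(s).
#' @param rna_sequence RNA string over A/C/G/U.
#' @param scheme A [labeling_scheme()].
#' @param spectra Character vector of spectrum file identifiers (>= 1).
#' @param enzyme Enzyme name.
#' @param missed_cleavages Maximum missed cleavages (>= 0).
#' @param ms1_tol_ppm Precursor mass tolerance, ppm (> 0).
#' @param ms2_tol_common_da,ms2_tol_xlink_da Fragment tolerances, Da (> 0).
#' @param spectra_group Optional sample-type label per spectrum file
#'   (recycled if scalar).
#' @param out_dir Output directory for generated files.
#' @return Object of class `search_config`.
#' @export
search_config <- function(fasta, rna_sequence, scheme, spectra,
                          enzyme = "trypsin", missed_cleavages = 2L,
                          ms1_tol_ppm = 10, ms2_tol_common_da = 0.2,
                          ms2_tol_xlink_da = 0.3,
                          spectra_group = "default", out_dir = ".") {
  stopifnot(is.character(fasta), length(fasta) >= 1L,
            inherits(scheme, "labeling_scheme"),
            is.character(spectra), length(spectra) >= 1L)
  .check_rna_sequence(rna_sequence)
  if (missed_cleavages < 0) stop("missed_cleavages must be >= 0")
  if (ms1_tol_ppm <= 0 || ms2_tol_common_da <= 0 || ms2_tol_xlink_da <= 0) {
    stop("tolerances must be positive")
  }
  spectra_group <- rep_len(spectra_group, length(spectra))
  structure(list(
    fasta = fasta, rna_sequence = toupper(rna_sequence), scheme = scheme,
    spectra = spectra, enzyme = enzyme,
    missed_cleavages = as.integer(missed_cleavages),
    ms1_tol_ppm = ms1_tol_ppm, ms2_tol_common_da = ms2_tol_common_da,
    ms2_tol_xlink_da = ms2_tol_xlink_da,
    spectra_group = spectra_group, out_dir = out_dir
  ), class = "search_config")
}

.param_doc_lines <- function(config, group_id, delta, species_lines,
                             light_only = FALSE) {
  c(
    sprintf("group_id=%s", group_id),
    sprintf("delta_mass_da=%s", fmt_num(delta)),
    sprintf("light_only=%s", tolower(as.character(light_only))),
    sprintf("enzyme=%s", config$enzyme),
    sprintf("missed_cleavages=%d", config$missed_cleavages),
    sprintf("ms1_tol_ppm=%s", fmt_num(config$ms1_tol_ppm, 3)),
    sprintf("ms2_tol_common_da=%s", fmt_num(config$ms2_tol_common_da, 3)),
    sprintf("ms2_tol_xlink_da=%s", fmt_num(config$ms2_tol_xlink_da, 3)),
    sprintf("database=%s", paste(config$fasta, collapse = ";")),
    sprintf("spectra=%s", paste(config$spectra, collapse = ";")),
    sprintf("scheme=%s", config$scheme$name),
    species_lines
  )
}

#' Generate per-group search parameter files and a manifest
#'
#' Writes one sub-directory per search group containing a key-value parameter
#' document (one `monolinkmass=<light>,<delta>` line per member species, plus
#' shared engine settings), and a top-level `manifest.tsv` listing every
#' document. Regeneration over an existing tree with identical inputs is
#' byte-identical.
#'
#' @param config A [search_config()].
#' @param groups Non-empty list of `search_group` from [group_by_delta()].
#' @return Object of class `parameter_file_set`: `manifest` (data.table with
#'   columns group_id, delta_mass_da, param_path, light_only, spectra_group),
#'   `manifest_path`, `out_dir`.
#' @export
generate_search_params <- function(config, groups) {
  stopifnot(inherits(config, "search_config"))
  if (length(groups) == 0L) stop("empty group list")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2) != 0) {
    stop("output directory not writable: ", out_dir)
  }
  sg <- paste(unique(config$spectra_group), collapse = ";")
  rows <- lapply(groups, function(g) {
    gdir <- file.path(out_dir, g$group_id)
    dir.create(gdir, showWarnings = FALSE)
    sp_lines <- vapply(g$species, function(s) {
      sprintf("monolinkmass=%s,%s  # %s %s",
              fmt_num(s$light_mass_da), fmt_num(s$delta_mass_da),
              comp_tag(s$composition), s$loss$name)
    }, character(1))
    ppath <- file.path(gdir, "search.params")
    writeLines(.param_doc_lines(config, g$group_id, g$delta_mass_da,
                                sp_lines), ppath)
    data.table::data.table(
      group_id = g$group_id,
      delta_mass_da = fmt_num(g$delta_mass_da),
      param_path = file.path(g$group_id, "search.params"),
      light_only = "false",
      spectra_group = sg
    )
  })
  manifest <- data.table::rbindlist(rows)
  mpath <- file.path(out_dir, "manifest.tsv")
  data.table::fwrite(manifest, mpath, sep = "\t")
  structure(list(manifest = manifest, manifest_path = mpath,
                 out_dir = out_dir),
            class = "parameter_file_set")
}

#' Append a light-only (unmodified peptide) search definition
#'
#' Adds one search with a single modification of mass 0 Da and the
#' isotope-pair requirement disabled, flagged `light_only` in the manifest.
#' Used to score unmodified peptides against the same database so that
#' external rescoring sees both populations.
#'
#' @param pfs A `parameter_file_set` from [generate_search_params()].
#' @param config The same [search_config()].
#' @return The updated `parameter_file_set`.
#' @export
generate_light_only_search <- function(pfs, config) {
  stopifnot(inherits(pfs, "parameter_file_set"),
            inherits(config, "search_config"))
  gid <- "G_light_only"
  gdir <- file.path(pfs$out_dir, gid)
  dir.create(gdir, showWarnings = FALSE)
  ppath <- file.path(gdir, "search.params")
  writeLines(.param_doc_lines(config, gid, 0,
                              "monolinkmass=0.000000,0.000000  # light-only",
                              light_only = TRUE), ppath)
  row <- data.table::data.table(
    group_id = gid, delta_mass_da = fmt_num(0),
    param_path = file.path(gid, "search.params"),
    light_only = "true",
    spectra_group = paste(unique(config$spectra_group), collapse = ";")
  )
  pfs$manifest <- data.table::rbindlist(list(pfs$manifest, row))
  data.table::fwrite(pfs$manifest, pfs$manifest_path, sep = "\t")
  pfs
}

#' Read a manifest written by [generate_search_params()]
#' @param path Path to `manifest.tsv`.
#' @return data.table with `light_only` as logical.
#' @export
read_manifest <- function(path) {
  m <- data.table::fread(path, sep = "\t",
                         colClasses = list(character = "delta_mass_da"))
  m$light_only <- m$light_only == "true" | m$light_only == "TRUE"
  m
}

.read_fasta_checked <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L && !startsWith(lines[1], ">")) {
    stop("malformed FASTA record 1: file does not start with '>'")
  }
  hdr <- which(startsWith(lines, ">"))
  for (i in seq_along(hdr)) {
    to <- if (i < length(hdr)) hdr[i + 1] - 1L else length(lines)
    if (to < hdr[i] + 1L) {
      stop("malformed FASTA record ", i, ": header with no sequence")
    }
  }
  Biostrings::readAAStringSet(path)
}

#' Build a decoy protein database
#'
#' One decoy record per target record, headers prefixed with `decoy_tag`.
#' `reverse` reverses each sequence; `shuffle` permutes residues
#' seed-deterministically; `reverse_then_shuffle` applies both in order.
#' Residue composition and length are preserved in all modes.
#'
#' @param fasta_in Path to target FASTA.
#' @param fasta_out Path for the decoy FASTA.
#' @param mode One of `"reverse"`, `"shuffle"`, `"reverse_then_shuffle"`.
#' @param seed Integer seed for shuffling.
#' @param decoy_tag Header prefix for decoy records (default `"decoy_"`).
#' @return `fasta_out`, invisibly.
#' @export
make_decoy_db <- function(fasta_in, fasta_out,
                          mode = c("reverse", "shuffle",
                                   "reverse_then_shuffle"),
                          seed = 1L, decoy_tag = "decoy_") {
  mode <- match.arg(mode)
  aa <- .read_fasta_checked(fasta_in)
  if (length(aa) == 0L) {
    warning("empty FASTA input; writing empty decoy database")
    writeLines(character(0), fasta_out)
    return(invisible(fasta_out))
  }
  seqs <- as.character(aa)
  out <- with_local_seed(seed, {
    vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      if (mode %in% c("reverse", "reverse_then_shuffle")) ch <- rev(ch)
      if (mode %in% c("shuffle", "reverse_then_shuffle")) ch <- sample(ch)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  decoys <- Biostrings::AAStringSet(out)
  names(decoys) <- paste0(decoy_tag, names(aa))
  Biostrings::writeXStringSet(decoys, fasta_out, width = 80L)
  invisible(fasta_out)
}
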