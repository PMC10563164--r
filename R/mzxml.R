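# Minimal mzXML reader/writer. The pre-installed stack has no proteomics
# raw-data IO package, so this implements the small subset of mzXML the
# precursor-level operations need: scan number, MS level, retention time,
# precursor m/z + charge, and base64 network-order peak arrays.

.enc_peaks <- function(mz, intensity) {
  if (length(mz) == 0L) return("")
  inter <- as.numeric(rbind(mz, intensity))
  jsonlite::base64_enc(writeBin(inter, raw(), size = 8, endian = "big"))
}

.dec_peaks <- function(b64, precision = 64L) {
  if (is.na(b64) || b64 == "") {
    return(list(mz = numeric(0), intensity = numeric(0)))
  }
  raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
  size <- if (precision == 32L) 4L else 8L
  vals <- readBin(raw, "numeric", n = length(raw) %/% size, size = size,
                  endian = "big")
  idx <- seq_along(vals)
  list(mz = vals[idx %% 2 == 1], intensity = vals[idx %% 2 == 0])
}

.fmt_rt <- function(seconds) sprintf("PT%.4fS", seconds)

.parse_rt <- function(s) {
  if (is.na(s)) return(NA_real_)
  as.numeric(sub("S$", "", sub("^PT", "", s)))
}

#' Write scans to a minimal mzXML file
#'
#' @param scans List of scans; each a list with `num` (int), `ms_level` (1 or
#'   2), `rt_s` (seconds), `mz`, `intensity` (numeric vectors), and for MS2
#'   scans `precursor_mz` and `precursor_charge`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzxml <- function(scans, path) {
  lines <- c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">',
    sprintf(' <msRun scanCount="%d">', length(scans))
  )
  for (sc in scans) {
    lines <- c(lines, sprintf(
      '  <scan num="%d" msLevel="%d" retentionTime="%s" peaksCount="%d">',
      sc$num, sc$ms_level, .fmt_rt(sc$rt_s), length(sc$mz)))
    if (sc$ms_level >= 2L && !is.null(sc$precursor_mz)) {
      lines <- c(lines, sprintf(
        '   <precursorMz precursorCharge="%d">%.8f</precursorMz>',
        sc$precursor_charge, sc$precursor_mz))
    }
    lines <- c(lines, sprintf(
      '   <peaks precision="64" byteOrder="network" contentType="m/z-int">%s</peaks>',
      .enc_peaks(sc$mz, sc$intensity)),
      "  </scan>")
  }
  lines <- c(lines, " </msRun>", "</mzXML>")
  writeLines(lines, path)
  invisible(path)
}

#' Read all scans from an mzXML file
#'
#' @param path mzXML path.
#' @return List of scans in the representation [write_mzxml()] accepts.
#' @export
read_mzxml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot read mzXML '", path, "': ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  scan_nodes <- xml2::xml_find_all(doc, ".//scan")
  lapply(scan_nodes, function(node) {
    peaks_node <- xml2::xml_find_first(node, "./peaks")
    precision <- as.integer(xml2::xml_attr(peaks_node, "precision"))
    if (is.na(precision)) precision <- 64L
    pk <- .dec_peaks(xml2::xml_text(peaks_node), precision)
    prec_node <- xml2::xml_find_first(node, "./precursorMz")
    has_prec <- !inherits(prec_node, "xml_missing")
    list(
      num = as.integer(xml2::xml_attr(node, "num")),
      ms_level = as.integer(xml2::xml_attr(node, "msLevel")),
      rt_s = .parse_rt(xml2::xml_attr(node, "retentionTime")),
      precursor_mz = if (has_prec) as.numeric(xml2::xml_text(prec_node)) else NULL,
      precursor_charge = if (has_prec)
        as.integer(xml2::xml_attr(prec_node, "precursorCharge")) else NULL,
      mz = pk$mz,
      intensity = pk$intensity
    )
  })
}

#' Extract precursor records from an mzXML file
#'
#' One record per MS2 scan carrying precursor metadata; MS2 scans without it
#' are skipped with a warning reporting the count.
#'
#' @param mzxml_path mzXML path.
#' @return `data.table` with columns scan_id, precursor_mz, charge,
#'   retention_time (seconds), source_file; ordered by scan_id.
#' @export
read_precursors <- function(mzxml_path) {
  scans <- read_mzxml(mzxml_path)
  ms2 <- Filter(function(s) identical(s$ms_level, 2L), scans)
  missing <- vapply(ms2, function(s)
    is.null(s$precursor_mz) || is.na(s$precursor_mz), logical(1))
  if (any(missing)) {
    warning(sum(missing), " MS2 scan(s) lacked precursor information; skipped")
    ms2 <- ms2[!missing]
  }
  if (length(ms2) == 0L) {
    return(data.table::data.table(
      scan_id = integer(), precursor_mz = numeric(), charge = integer(),
      retention_time = numeric(), source_file = character()))
  }
  dt <- data.table::rbindlist(lapply(ms2, function(s) data.table::data.table(
    scan_id = s$num, precursor_mz = s$precursor_mz, charge = s$precursor_charge,
    retention_time = s$rt_s, source_file = basename(mzxml_path))))
  data.table::setorder(dt, scan_id)
  dt[]
}

#' Shift every m/z value in an mzXML file (decoy dataset generation)
#'
#' Adds `shift` to every precursor and fragment m/z, preserving retention
#' times, intensities, charges and scan numbering. Shifting real data by a
#' constant (e.g. +10 m/z) produces a dataset in which no true identification
#' should survive, a negative control for the search pipeline.
#'
#' @param mzxml_in,mzxml_out Input/output paths.
#' @param shift m/z shift in Th (default +10).
#' @return List with `n_scans`, `shift`, `out` (invisible path).
#' @export
shift_mz_decoy <- function(mzxml_in, mzxml_out, shift = 10) {
  scans <- read_mzxml(mzxml_in)
  all_mz <- unlist(lapply(scans, function(s)
    c(s$mz, if (!is.null(s$precursor_mz)) s$precursor_mz)))
  if (length(all_mz) > 0L && min(all_mz) + shift <= 0) {
    stop("shift of ", shift, " would produce non-positive m/z (min input ",
         fmt_num(min(all_mz), 4), ")")
  }
  shifted <- lapply(scans, function(s) {
    s$mz <- s$mz + shift
    if (!is.null(s$precursor_mz)) s$precursor_mz <- s$precursor_mz + shift
    s
  })
  write_mzxml(shifted, mzxml_out)
  invisible(list(n_scans = length(scans), shift = shift, out = mzxml_out))
}

#' Find light/heavy isotope scan pairs among precursors
#'
#' A pair is two equal-charge MS2 precursors whose neutral mass difference
#' matches one of the expected label delta masses within a ppm tolerance
#' (computed on the light neutral mass, `ppm = |(heavy - light) * z - delta| /
#' (light * z) * 1e6`) and whose retention times differ by at most
#' `rt_tol_s`. A scan may appear in multiple candidate pairs; the list is
#' exhaustive and disambiguation is left to the downstream search.
#'
#' @param records Precursor table from [read_precursors()] (columns scan_id,
#'   precursor_mz, charge, retention_time).
#' @param deltas Positive expected delta masses, Da.
#' @param ppm_tol Mass-shift tolerance in ppm (default 10).
#' @param rt_tol_s Maximum retention-time gap in seconds (default 60).
#' @return `data.table` with columns light_scan, heavy_scan, delta_da,
#'   ppm_error, rt_gap_s, charge; sorted by light_scan, heavy_scan, delta_da.
#' @export
find_isotope_pairs <- function(records, deltas, ppm_tol = 10, rt_tol_s = 60) {
  stopifnot(all(deltas > 0), ppm_tol > 0, rt_tol_s > 0)
  empty <- data.table::data.table(
    light_scan = integer(), heavy_scan = integer(), delta_da = numeric(),
    ppm_error = numeric(), rt_gap_s = numeric(), charge = integer())
  if (is.null(records) || nrow(records) == 0L) return(empty)
  rec <- data.table::as.data.table(records)
  out <- list()
  for (z in sort(unique(rec$charge))) {
    sub <- rec[rec$charge == z]
    data.table::setorder(sub, precursor_mz)
    mz <- sub$precursor_mz
    rt <- sub$retention_time
    n <- nrow(sub)
    for (delta in deltas) {
      off <- delta / z
      for (i in seq_len(n)) {
        # heavy candidates: mz within off +/- ppm window around mz[i] + off
        w <- ppm_tol * 1e-6 * mz[i]
        lo <- findInterval(mz[i] + off - w, mz) + 1L
        hi <- findInterval(mz[i] + off + w, mz)
        if (hi < lo) next
        for (j in seq.int(lo, hi)) {
          if (j == i) next
          gap <- abs(rt[j] - rt[i])
          if (gap > rt_tol_s) next
          ppm <- abs((mz[j] - mz[i]) * z - delta) / (mz[i] * z) * 1e6
          if (ppm > ppm_tol) next
          out[[length(out) + 1L]] <- data.table::data.table(
            light_scan = sub$scan_id[i], heavy_scan = sub$scan_id[j],
            delta_da = delta, ppm_error = ppm, rt_gap_s = gap,
            charge = z)
        }
      }
    }
  }
  if (length(out) == 0L) return(empty)
  pairs <- data.table::rbindlist(out)
  data.table::setorder(pairs, light_scan, heavy_scan, delta_da)
  unique(pairs)
}
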