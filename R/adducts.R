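# RNA adduct chemistry: nucleotide compositions, neutral losses, isotope
# labeling schemes, adduct species with light/heavy masses, and grouping of
# species into parallel searches by delta mass.

.RNA_BASES <- c("A", "C", "G", "U")

# Nucleoside-5'-monophosphate formulas (free acid). An oligo of n residues is
# the sum of its NMPs minus (n-1) waters: 5'-phosphate, 3'-OH convention.
.NMP_FORMULA <- list(
  A = c(C = 10, H = 14, N = 5, O = 7, P = 1),
  C = c(C = 9,  H = 14, N = 3, O = 8, P = 1),
  G = c(C = 10, H = 14, N = 5, O = 8, P = 1),
  U = c(C = 9,  H = 13, N = 2, O = 9, P = 1)
)

.WATER <- c(H = 2, O = 1)
.HPO3 <- c(H = 1, P = 1, O = 3)

#' Nucleotide composition
#'
#' An order-free multiset of RNA bases, e.g. `CU` and `UC` are the same
#' composition. The canonical text form lists only non-zero bases in fixed
#' A, C, G, U order, e.g. `"C1U1"`.
#'
#' @param counts Named vector of base counts over A/C/G/U (zeros allowed).
#' @return Object of class `nt_composition`: an integer vector
#'   `c(A=,C=,G=,U=)` with a `tag` attribute.
#' @examples
#' nt_composition(c(U = 2, C = 1))
#' @export
nt_composition <- function(counts) {
  if (is.null(names(counts))) stop("counts must be named by base")
  bad <- setdiff(names(counts), .RNA_BASES)
  if (length(bad) > 0L) {
    stop("invalid base(s): ", paste(bad, collapse = ", "))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("base counts must be non-negative integers")
  }
  v <- setNames(integer(4), .RNA_BASES)
  v[names(counts)] <- as.integer(counts)
  structure(v, tag = .comp_tag(v), class = "nt_composition")
}

.comp_tag <- function(v) {
  nz <- v > 0
  if (!any(nz)) return("")
  paste0(.RNA_BASES[nz], v[nz], collapse = "")
}

#' @export
print.nt_composition <- function(x, ...) {
  cat("<nt_composition>", comp_tag(x), " (length", comp_length(x), ")\n")
  invisible(x)
}

#' Canonical tag of a composition
#' @param comp An `nt_composition`.
#' @return Character scalar like `"C1U2"`.
#' @export
comp_tag <- function(comp) attr(comp, "tag")

#' Number of nucleotides in a composition
#' @param comp An `nt_composition`.
#' @return Integer length (sum of base counts).
#' @export
comp_length <- function(comp) sum(unclass(comp))

#' Parse a canonical composition tag
#' @param tag Character scalar like `"C1U1"` or `"U"` (count 1 implied).
#' @return An `nt_composition`.
#' @export
parse_comp_tag <- function(tag) {
  stopifnot(is.character(tag), length(tag) == 1L)
  tag <- toupper(gsub("\\s", "", tag))
  if (tag == "") stop("empty composition tag")
  m <- gregexpr("([ACGU])([0-9]*)", tag)[[1]]
  if (sum(attr(m, "match.length")) != nchar(tag)) {
    stop("cannot parse composition tag: ", tag)
  }
  parts <- regmatches(tag, list(m))[[1]]
  base <- substr(parts, 1, 1)
  num <- sub("^[ACGU]", "", parts)
  num <- ifelse(num == "", 1L, as.integer(num))
  counts <- tapply(num, base, sum)
  nt_composition(setNames(as.integer(counts), names(counts)))
}

.check_rna_sequence <- function(rna_sequence) {
  stopifnot(is.character(rna_sequence), length(rna_sequence) == 1L)
  s <- toupper(gsub("\\s", "", rna_sequence))
  if (nchar(s) == 0L) stop("empty RNA sequence")
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% .RNA_BASES)
  if (length(bad) > 0L) {
    stop(sprintf("invalid base '%s' at position %d", chars[bad[1]], bad[1]))
  }
  chars
}

#' Enumerate nucleotide compositions of an RNA sequence
#'
#' Returns the set of distinct base compositions over all contiguous
#' substrings of the input with lengths between `min_len` and `max_len`.
#' These are the candidate RNA adduct species a nuclease digest of the input
#' can leave attached to a cross-linked peptide.
#'
#' @param rna_sequence RNA string over A/C/G/U (case-insensitive).
#' @param min_len,max_len Substring length range, `1 <= min_len <= max_len <=
#'   nchar(rna_sequence)`.
#' @return Named list of `nt_composition`, named by canonical tag, ordered by
#'   length then tag.
#' @examples
#' names(enumerate_compositions("UCUCU", 1, 4))
#' @export
enumerate_compositions <- function(rna_sequence, min_len = 1L, max_len = 4L) {
  chars <- .check_rna_sequence(rna_sequence)
  n <- length(chars)
  if (min_len < 1L || min_len > max_len) {
    stop("need 1 <= min_len <= max_len")
  }
  if (max_len > n) {
    stop("max_len (", max_len, ") exceeds sequence length (", n, ")")
  }
  seen <- new.env(parent = emptyenv())
  # sliding window per length, updating counts incrementally
  for (k in seq.int(min_len, max_len)) {
    cnt <- setNames(integer(4), .RNA_BASES)
    win <- chars[seq_len(k)]
    for (b in win) cnt[b] <- cnt[b] + 1L
    assign(.comp_tag(cnt), cnt, envir = seen)
    if (n > k) {
      for (i in seq.int(2L, n - k + 1L)) {
        cnt[chars[i - 1L]] <- cnt[chars[i - 1L]] - 1L
        cnt[chars[i + k - 1L]] <- cnt[chars[i + k - 1L]] + 1L
        tag <- .comp_tag(cnt)
        if (!exists(tag, envir = seen, inherits = FALSE)) {
          assign(tag, cnt, envir = seen)
        }
      }
    }
  }
  tags <- ls(seen)
  comps <- lapply(tags, function(t) nt_composition(get(t, envir = seen)))
  names(comps) <- tags
  lens <- vapply(comps, comp_length, integer(1))
  comps[order(lens, tags)]
}

#' Neutral loss specification
#'
#' @param name Short tag, e.g. `"-H2O"`; `"none"` is the null loss.
#' @param formula_delta `chem_formula` subtracted from the oligonucleotide
#'   formula (empty for the null loss).
#' @return Object of class `loss_spec`.
#' @export
loss_spec <- function(name, formula_delta = chem_formula()) {
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0,
            inherits(formula_delta, "chem_formula"))
  structure(list(name = name, formula_delta = formula_delta),
            class = "loss_spec")
}

#' Default neutral loss table
#'
#' Losses commonly seen for nucleic-acid adducts during ionization and
#' fragmentation: none, water, metaphosphate, phosphate. User-extensible —
#' pass any list of [loss_spec()] objects where a loss table is accepted.
#' @return Named list of `loss_spec`.
#' @export
default_losses <- function() {
  list(
    none = loss_spec("none"),
    `-H2O` = loss_spec("-H2O", chem_formula(.WATER)),
    `-HPO3` = loss_spec("-HPO3", chem_formula(.HPO3)),
    `-H3PO4` = loss_spec("-H3PO4", chem_formula(c(H = 3, P = 1, O = 4)))
  )
}

#' Isotope labeling scheme
#'
#' Describes which atoms of each nucleotide residue are heavy in the labeled
#' form of the RNA, plus optional per-adduct constant substitutions (applied
#' once per adduct regardless of length, e.g. one 18O on the terminal
#' phosphate).
#'
#' Presets:
#' * `none` — unlabeled; every delta mass is 0.
#' * `metabolic_13C15N` — all ribose and base carbons and all nitrogens heavy
#'   (A: 10C 5N, C: 9C 3N, G: 10C 5N, U: 9C 2N per residue).
#' * `ribose_13C` — the five ribose carbons of every residue heavy.
#' * `phosphate_18O` — one 18O per adduct on the appended phosphate
#'   (delta about 2.00425 Da); count configurable via `per_adduct`.
#'
#' @param name Preset name or `"custom"`.
#' @param per_base For `"custom"`: named list base -> named integer vector of
#'   heavy-atom counts (e.g. `list(U = c(C = 9, N = 2))`).
#' @param per_adduct Named integer vector of per-adduct heavy substitutions.
#' @return Object of class `labeling_scheme`.
#' @export
labeling_scheme <- function(name = c("none", "metabolic_13C15N", "ribose_13C",
                                     "phosphate_18O", "custom"),
                            per_base = NULL, per_adduct = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    none = list(per_base = list(), per_adduct = integer()),
    metabolic_13C15N = list(
      per_base = list(A = c(C = 10, N = 5), C = c(C = 9, N = 3),
                      G = c(C = 10, N = 5), U = c(C = 9, N = 2)),
      per_adduct = integer()),
    ribose_13C = list(
      per_base = list(A = c(C = 5), C = c(C = 5), G = c(C = 5), U = c(C = 5)),
      per_adduct = integer()),
    phosphate_18O = list(per_base = list(), per_adduct = c(O = 1)),
    custom = list(per_base = list(), per_adduct = integer())
  )
  if (!is.null(per_base)) preset$per_base <- per_base
  if (!is.null(per_adduct)) preset$per_adduct <- per_adduct
  for (b in names(preset$per_base)) {
    if (!b %in% .RNA_BASES) stop("scheme references unknown base: ", b)
    avail <- .NMP_FORMULA[[b]]
    sub <- preset$per_base[[b]]
    over <- sub > avail[names(sub)] | is.na(avail[names(sub)])
    if (any(over)) {
      stop("scheme substitutes more atoms than base ", b, " provides")
    }
  }
  structure(list(name = name, per_base = preset$per_base,
                 per_adduct = preset$per_adduct),
            class = "labeling_scheme")
}

#' Build one RNA adduct species
#'
#' Computes the light and heavy elemental formulas and monoisotopic masses of
#' an RNA-derived peptide modification: the oligonucleotide of the given
#' composition (5'-monophosphate, 3'-OH by default), minus the neutral loss,
#' with the labeling scheme's heavy substitutions applied. Heavy substitutions
#' are capped at the atoms actually present after the loss, so a loss that
#' removes labeled atoms reduces the delta mass accordingly.
#'
#' @param composition `nt_composition` of length >= 1.
#' @param loss A [loss_spec()]; default none.
#' @param scheme A [labeling_scheme()].
#' @param terminus `"5p_phosphate"` (default; nuclease-product convention) or
#'   `"5p_OH"` (subtracts one HPO3).
#' @return Object of class `adduct_species` with fields `composition`, `loss`,
#'   `light_formula`, `heavy_formula`, `light_mass_da`, `heavy_mass_da`,
#'   `delta_mass_da`.
#' @examples
#' u <- build_adduct_species(parse_comp_tag("U"),
#'                           scheme = labeling_scheme("metabolic_13C15N"))
#' round(u$light_mass_da, 4)  # 324.0359
#' round(u$delta_mass_da, 4)  # 11.0243
#' @export
build_adduct_species <- function(composition,
                                 loss = loss_spec("none"),
                                 scheme = labeling_scheme("none"),
                                 terminus = c("5p_phosphate", "5p_OH")) {
  stopifnot(inherits(composition, "nt_composition"),
            inherits(loss, "loss_spec"),
            inherits(scheme, "labeling_scheme"))
  terminus <- match.arg(terminus)
  n <- comp_length(composition)
  if (n < 1L) stop("composition must contain at least one nucleotide")

  light <- chem_formula()
  for (b in .RNA_BASES) {
    k <- unclass(composition)[[b]]
    if (k > 0L) {
      light <- formula_add(light,
                           formula_multiply(chem_formula(.NMP_FORMULA[[b]]), k))
    }
  }
  light <- formula_subtract(light,
                            formula_multiply(chem_formula(.WATER), n - 1L))
  if (terminus == "5p_OH") {
    light <- formula_subtract(light, chem_formula(.HPO3))
  }
  light <- formula_subtract(light, loss$formula_delta)

  # heavy substitution budget: per-base contributions plus per-adduct
  # constants, capped at the atoms remaining after the loss
  sub <- setNames(integer(0), character(0))
  for (b in .RNA_BASES) {
    k <- unclass(composition)[[b]]
    pb <- scheme$per_base[[b]]
    if (k > 0L && !is.null(pb)) {
      sub <- .merge_counts(sub, setNames(as.integer(pb) * k, names(pb)), `+`)
    }
  }
  if (length(scheme$per_adduct) > 0L) {
    sub <- .merge_counts(sub, scheme$per_adduct, `+`)
  }
  if (length(sub) > 0L) {
    avail <- setNames(rep(0L, length(sub)), names(sub))
    ok <- names(sub) %in% names(light$counts)
    avail[ok] <- light$counts[names(sub)[ok]]
    sub <- pmin(sub, avail)
    sub <- sub[sub > 0]
  }
  heavy <- chem_formula(light$counts, .merge_counts(light$heavy, sub, `+`))

  lm <- formula_mass(light)
  hm <- formula_mass(heavy)
  structure(list(
    composition = composition,
    loss = loss,
    light_formula = light,
    heavy_formula = heavy,
    light_mass_da = lm,
    heavy_mass_da = hm,
    delta_mass_da = hm - lm
  ), class = "adduct_species")
}

#' @export
print.adduct_species <- function(x, ...) {
  cat(sprintf("<adduct_species> %s %s  light %.6f Da  delta %.6f Da\n",
              comp_tag(x$composition), x$loss$name,
              x$light_mass_da, x$delta_mass_da))
  invisible(x)
}

#' Enumerate all adduct species for an RNA sequence
#'
#' Convenience wrapper: [enumerate_compositions()] crossed with a loss table,
#' each built by [build_adduct_species()]. Species whose loss is not
#' subtractable from the oligo (cannot occur) are skipped.
#'
#' @inheritParams enumerate_compositions
#' @inheritParams build_adduct_species
#' @param losses List of [loss_spec()]; default [default_losses()].
#' @return List of `adduct_species`, deterministic order (composition length,
#'   tag, loss table order).
#' @export
enumerate_adduct_species <- function(rna_sequence, scheme,
                                     min_len = 1L, max_len = 4L,
                                     losses = default_losses(),
                                     terminus = "5p_phosphate") {
  comps <- enumerate_compositions(rna_sequence, min_len, max_len)
  out <- list()
  for (comp in comps) {
    for (loss in losses) {
      sp <- tryCatch(
        build_adduct_species(comp, loss, scheme, terminus),
        error = function(e) NULL
      )
      if (!is.null(sp)) out[[length(out) + 1L]] <- sp
    }
  }
  out
}

#' Group adduct species into parallel searches by delta mass
#'
#' Species whose heavy-light delta masses agree within `tol_da` are searched
#' together (one isotope-pair delta per search). Grouping is a partition:
#' species are sorted by delta and a new group starts whenever the delta
#' exceeds the first member of the current group by more than `tol_da`.
#' Assignment is independent of input order.
#'
#' @param species List of `adduct_species` from one labeling scheme.
#' @param tol_da Grouping tolerance in Da (default 1e-4).
#' @return List of `search_group` objects: `group_id`, `delta_mass_da` (mean
#'   of members), `species`. Sorted by ascending delta.
#' @export
group_by_delta <- function(species, tol_da = 1e-4) {
  stopifnot(is.list(species), tol_da > 0)
  if (length(species) == 0L) return(list())
  deltas <- vapply(species, function(s) s$delta_mass_da, numeric(1))
  tags <- vapply(species, function(s)
    paste(comp_tag(s$composition), s$loss$name), character(1))
  ord <- order(deltas, tags)
  species <- species[ord]
  deltas <- deltas[ord]

  groups <- list()
  start <- 1L
  for (i in seq_along(species)) {
    if (deltas[i] - deltas[start] > tol_da) {
      groups[[length(groups) + 1L]] <- seq.int(start, i - 1L)
      start <- i
    }
  }
  groups[[length(groups) + 1L]] <- seq.int(start, length(species))

  lapply(seq_along(groups), function(g) {
    idx <- groups[[g]]
    structure(list(
      group_id = sprintf("G%03d", g),
      delta_mass_da = mean(deltas[idx]),
      species = species[idx]
    ), class = "search_group")
  })
}

#' @export
print.search_group <- function(x, ...) {
  cat(sprintf("<search_group> %s  delta %.6f Da  %d species\n",
              x$group_id, x$delta_mass_da, length(x$species)))
  invisible(x)
}

#' Tabulate adduct species and their search groups
#'
#' @param groups List of `search_group` from [group_by_delta()].
#' @return `data.table` with columns composition, loss, light_mass_da,
#'   heavy_mass_da, delta_mass_da, group_id.
#' @export
adduct_table <- function(groups) {
  rows <- lapply(groups, function(g) {
    data.table::rbindlist(lapply(g$species, function(s) data.table::data.table(
      composition = comp_tag(s$composition),
      loss = s$loss$name,
      light_mass_da = s$light_mass_da,
      heavy_mass_da = s$heavy_mass_da,
      delta_mass_da = s$delta_mass_da,
      group_id = g$group_id
    )))
  })
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L) {
    out <- data.table::data.table(
      composition = character(), loss = character(),
      light_mass_da = numeric(), heavy_mass_da = numeric(),
      delta_mass_da = numeric(), group_id = character())
  }
  out
}

#' Write an adduct table as TSV (masses to 6 decimal places)
#' @param groups List of `search_group`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_adduct_table <- function(groups, path) {
  dt <- adduct_table(groups)
  for (col in c("light_mass_da", "heavy_mass_da", "delta_mass_da")) {
    data.table::set(dt, j = col, value = sprintf("%.6f", dt[[col]]))
  }
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Generate a short RNA sequence covering all compositions up to a length
#'
#' Produces a deterministic sequence that contains, as contiguous substrings,
#' at least one representative of every base composition of every length 1 to
#' `k_max` — the "design RNA" used to search for arbitrary adducts when the
#' true RNA is unknown. Greedy construction: repeatedly append the base that
#' covers the most still-uncovered compositions (ties broken alphabetically);
#' if no single base helps, append the sorted bases of the first uncovered
#' composition. Minimality is not claimed.
#'
#' @param k_max Maximum composition length (>= 1).
#' @param alphabet Character vector of bases (subset of A/C/G/U).
#' @return Character scalar RNA sequence.
#' @examples
#' s <- generate_covering_rna(2, c("A", "C"))
#' @export
generate_covering_rna <- function(k_max, alphabet = c("A", "C", "G", "U")) {
  stopifnot(k_max >= 1, length(alphabet) >= 1)
  alphabet <- sort(unique(toupper(alphabet)))
  if (!all(alphabet %in% .RNA_BASES)) stop("alphabet must be RNA bases")

  # all multisets of sizes 1..k_max over the alphabet
  uncovered <- new.env(parent = emptyenv())
  add_multisets <- function(k) {
    grid <- do.call(expand.grid, c(rep(list(alphabet), k),
                                   stringsAsFactors = FALSE))
    for (i in seq_len(nrow(grid))) {
      v <- setNames(integer(4), .RNA_BASES)
      for (b in as.character(grid[i, ])) v[b] <- v[b] + 1L
      assign(.comp_tag(v), TRUE, envir = uncovered)
    }
  }
  for (k in seq_len(k_max)) add_multisets(k)

  seq_chars <- character(0)
  suffix_tags <- function(chars) {
    # composition tags of all suffixes of `chars` up to length k_max
    n <- length(chars)
    out <- character(0)
    v <- setNames(integer(4), .RNA_BASES)
    for (k in seq_len(min(k_max, n))) {
      v[chars[n - k + 1L]] <- v[chars[n - k + 1L]] + 1L
      out <- c(out, .comp_tag(v))
    }
    out
  }
  while (length(ls(uncovered)) > 0L) {
    gains <- vapply(alphabet, function(b) {
      tags <- suffix_tags(c(seq_chars, b))
      sum(vapply(tags, exists, logical(1),
                 envir = uncovered, inherits = FALSE))
    }, numeric(1))
    if (max(gains) > 0) {
      b <- alphabet[which.max(gains)]  # which.max: first = alphabetical tie-break
      seq_chars <- c(seq_chars, b)
      for (tag in suffix_tags(seq_chars)) {
        if (exists(tag, envir = uncovered, inherits = FALSE)) {
          rm(list = tag, envir = uncovered)
        }
      }
    } else {
      # append the sorted bases of the first uncovered composition wholesale
      tag <- ls(uncovered)[1]
      comp <- parse_comp_tag(tag)
      for (b in .RNA_BASES) {
        seq_chars <- c(seq_chars, rep(b, unclass(comp)[[b]]))
      }
      # remove everything the new suffixes now cover
      n <- length(seq_chars)
      for (i in seq_len(n)) {
        tags <- suffix_tags(seq_chars[seq_len(i)])
        for (t in tags) {
          if (exists(t, envir = uncovered, inherits = FALSE)) {
            rm(list = t, envir = uncovered)
          }
        }
      }
    }
  }
  paste(seq_chars, collapse = "")
}
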