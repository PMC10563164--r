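# Elemental formula arithmetic and monoisotopic mass calculation.
#
# A chem_formula is a pair of named integer vectors: `counts` (total atoms per
# element) and `heavy` (how many of those atoms carry the heavy isotope).
# Heavy counts never exceed the total count of their element, so light atom
# numbers are always `counts - heavy`.

# Monoisotopic masses (Da). Light values are the most abundant isotope; the
# heavy table maps element -> mass of the labeling isotope used in this field
# (13C, 15N, 18O, 2H).
.MONO_MASS <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100
)

.HEAVY_MASS <- c(
  H = 2.0141017778,   # 2H
  C = 13.0033548378,  # 13C
  N = 15.0001088982,  # 15N
  O = 17.9991610      # 18O
)

#' Construct an elemental formula
#'
#' @param counts Named integer vector of atom counts per element symbol
#'   (e.g. `c(C = 9, H = 13, N = 2, O = 9, P = 1)`).
#' @param heavy Named integer vector of heavy-isotope atom counts per element;
#'   each entry must not exceed the corresponding total in `counts`.
#' @return An object of class `chem_formula`.
#' @examples
#' chem_formula(c(H = 2, O = 1))                     # water
#' chem_formula(c(C = 9, N = 2), heavy = c(C = 9))   # all carbons 13C
#' @export
chem_formula <- function(counts = integer(), heavy = integer()) {
  counts <- .norm_counts(counts, "counts")
  heavy <- .norm_counts(heavy, "heavy")
  unknown <- setdiff(names(counts), names(.MONO_MASS))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  bad_heavy <- setdiff(names(heavy), names(.HEAVY_MASS))
  if (length(bad_heavy) > 0L) {
    stop("no heavy isotope defined for element(s): ",
         paste(bad_heavy, collapse = ", "))
  }
  over <- heavy > counts[names(heavy)] | is.na(counts[names(heavy)])
  if (any(over)) {
    stop("heavy count exceeds total atom count for: ",
         paste(names(heavy)[over], collapse = ", "))
  }
  structure(list(counts = counts, heavy = heavy), class = "chem_formula")
}

.norm_counts <- function(x, what) {
  if (length(x) == 0L) return(setNames(integer(0), character(0)))
  if (is.null(names(x)) || any(names(x) == "")) {
    stop(what, " must be a named vector of element counts")
  }
  if (any(x < 0) || any(x != round(x))) {
    stop(what, " must be non-negative integers")
  }
  x <- x[x > 0]
  v <- setNames(as.integer(x), names(x))
  v[order(names(v))]
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula>", format_formula(x), "\n")
  invisible(x)
}

#' Render a formula as a Hill-ish string, heavy atoms in brackets
#'
#' @param f A `chem_formula`.
#' @return Character scalar, e.g. `"C9H13N2O9P1 [13C9 15N2]"`.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "chem_formula"))
  if (length(f$counts) == 0L) return("(empty)")
  base <- paste0(names(f$counts), f$counts, collapse = "")
  if (length(f$heavy) == 0L) return(base)
  iso <- c(H = "2H", C = "13C", N = "15N", O = "18O")
  hv <- paste0(iso[names(f$heavy)], f$heavy, collapse = " ")
  paste0(base, " [", hv, "]")
}

.merge_counts <- function(a, b, op) {
  keys <- union(names(a), names(b))
  va <- setNames(rep(0L, length(keys)), keys)
  va[names(a)] <- a
  vb <- setNames(rep(0L, length(keys)), keys)
  vb[names(b)] <- b
  op(va, vb)
}

#' Add two formulas
#' @param a,b `chem_formula` objects.
#' @return Their `chem_formula` sum (counts and heavy counts add).
#' @export
formula_add <- function(a, b) {
  stopifnot(inherits(a, "chem_formula"), inherits(b, "chem_formula"))
  chem_formula(.merge_counts(a$counts, b$counts, `+`),
               .merge_counts(a$heavy, b$heavy, `+`))
}

#' Subtract one formula from another
#'
#' Subtraction is exact on integers; a result with any negative atom count is
#' an error. Heavy atoms are only removed insofar as the subtrahend carries
#' heavy counts itself; if removal leaves more heavy atoms than total atoms of
#' an element, the heavy count is capped at the total (a loss of unlabeled
#' atoms never removes labels).
#' @param a,b `chem_formula` objects (computes `a - b`).
#' @return A `chem_formula`.
#' @export
formula_subtract <- function(a, b) {
  stopifnot(inherits(a, "chem_formula"), inherits(b, "chem_formula"))
  counts <- .merge_counts(a$counts, b$counts, `-`)
  if (any(counts < 0)) {
    neg <- names(counts)[counts < 0]
    stop("subtraction yields negative count for: ", paste(neg, collapse = ", "))
  }
  heavy <- .merge_counts(a$heavy, b$heavy, `-`)
  if (any(heavy < 0)) {
    neg <- names(heavy)[heavy < 0]
    stop("subtraction yields negative heavy count for: ",
         paste(neg, collapse = ", "))
  }
  heavy <- heavy[heavy > 0]
  if (length(heavy) > 0L) {
    avail <- setNames(rep(0L, length(heavy)), names(heavy))
    ok <- names(heavy) %in% names(counts)
    avail[ok] <- counts[names(heavy)[ok]]
    heavy <- pmin(heavy, avail)
  }
  chem_formula(counts, heavy)
}

#' Scale a formula by a non-negative integer
#' @param f A `chem_formula`.
#' @param n Non-negative integer multiplier.
#' @return A `chem_formula`.
#' @export
formula_multiply <- function(f, n) {
  stopifnot(inherits(f, "chem_formula"), n >= 0, n == round(n))
  chem_formula(f$counts * as.integer(n), f$heavy * as.integer(n))
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of light-atom count times the monoisotopic atomic mass,
#' plus heavy-atom count times the heavy-isotope mass. The empty formula has
#' mass 0.
#' @param f A `chem_formula`.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass(chem_formula(c(H = 2, O = 1)))  # 18.01056
#' @export
formula_mass <- function(f) {
  stopifnot(inherits(f, "chem_formula"))
  if (length(f$counts) == 0L) return(0.0)
  light <- f$counts
  if (length(f$heavy) > 0L) {
    light[names(f$heavy)] <- light[names(f$heavy)] - f$heavy
  }
  sum(light * .MONO_MASS[names(light)]) +
    (if (length(f$heavy) > 0L) sum(f$heavy * .HEAVY_MASS[names(f$heavy)]) else 0)
}

#' Parse a simple formula string like "C9H13N2O9P"
#'
#' Element symbols followed by optional counts; no parentheses, no isotopes.
#' @param s Character scalar.
#' @return A `chem_formula`.
#' @export
parse_formula <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- gsub("\\s", "", s)
  if (s == "" || s == "0") return(chem_formula())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  parts <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse formula string: ", s)
  }
  sym <- sub("[0-9]*$", "", parts)
  num <- sub("^[A-Za-z]+", "", parts)
  num <- ifelse(num == "", 1L, as.integer(num))
  counts <- tapply(num, sym, sum)
  chem_formula(setNames(as.integer(counts), names(counts)))
}
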