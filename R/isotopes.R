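#' Load the element/isotope reference table
#'
#' Returns the per-element isotope table (nucleon number, exact mass in Da,
#' abundance as a fraction) used by every simulation in the package. Values
#' are read from a plain-text resource shipped with the package
#' (`extdata/isotopes.tsv`, NIST/CODATA atomic-mass evaluation) so that they
#' can be audited or overridden with a user-supplied file of the same layout.
#'
#' @param path Optional path to a custom tab-separated table with columns
#'   `element`, `nucleon`, `mass`, `abundance`. Defaults to the shipped table
#'   covering C, H, O, N, S and P.
#' @return An object of class `iso_table`: a named list, one entry per
#'   element, each a data frame with columns `nucleon`, `mass`, `abundance`
#'   sorted by ascending nucleon number.
#' @examples
#' tab <- iso_table()
#' tab$C
#' @export
iso_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "isotopes.tsv", package = "isosip",
                        mustWork = TRUE)
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("element", "nucleon", "mass", "abundance")
  if (!all(need %in% names(raw))) {
    stop("isotope table must have columns: ", paste(need, collapse = ", "))
  }
  tab <- lapply(split(raw[need[-1]], raw$element), function(d) {
    d <- d[order(d$nucleon), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  validate_iso_table(tab)
  structure(tab, class = "iso_table")
}

validate_iso_table <- function(tab) {
  for (el in names(tab)) {
    d <- tab[[el]]
    if (any(d$mass <= 0)) stop("non-positive isotope mass for ", el)
    if (any(d$abundance < 0 | d$abundance > 1)) {
      stop("abundance outside [0,1] for ", el)
    }
    if (abs(sum(d$abundance) - 1) > 1e-9) {
      stop("abundances of ", el, " sum to ", sum(d$abundance), ", not 1")
    }
    if (is.unsorted(d$nucleon, strictly = TRUE)) {
      stop("isotopes of ", el, " not sorted by nucleon number")
    }
  }
  invisible(tab)
}

#' @export
print.iso_table <- function(x, ...) {
  cat("Isotope table (", length(x), " elements: ",
      paste(names(x), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Set the enrichment level of one isotope of an element
#'
#' Implements an atom % enrichment specification: the abundance of the chosen
#' heavy isotope is set to `atom_fraction` and the remaining isotopes of that
#' element are rescaled in proportion to their natural ratios so the element
#' still sums to 1. Other elements are untouched; the input table is not
#' modified.
#'
#' @param table An `iso_table`.
#' @param element Element symbol, e.g. `"C"`.
#' @param nucleon Nucleon number of the isotope being enriched, e.g. `13`.
#' @param atom_fraction Target abundance of that isotope, in `[0, 1]`.
#' @return A new `iso_table` with the enrichment applied.
#' @examples
#' fifty <- apply_enrichment(iso_table(), "C", 13, 0.5)
#' fifty$C$abundance  # 0.5, 0.5
#' @export
apply_enrichment <- function(table, element, nucleon, atom_fraction) {
  stopifnot(inherits(table, "iso_table"))
  if (!is.numeric(atom_fraction) || length(atom_fraction) != 1 ||
      is.na(atom_fraction) || atom_fraction < 0 || atom_fraction > 1) {
    stop("atom_fraction must be a single number in [0, 1]")
  }
  if (!element %in% names(table)) {
    stop("element ", element, " not in isotope table")
  }
  d <- table[[element]]
  i <- match(nucleon, d$nucleon)
  if (is.na(i)) {
    stop("nucleon ", nucleon, " is not a listed isotope of ", element)
  }
  rest <- d$abundance[-i]
  total_rest <- sum(rest)
  if (total_rest <= 0) {
    if (atom_fraction < 1) {
      stop("cannot set ", element, nucleon, " below 1: no other isotopes ",
           "with non-zero natural abundance to absorb the remainder")
    }
    d$abundance[i] <- 1
  } else {
    d$abundance[i] <- atom_fraction
    d$abundance[-i] <- rest / total_rest * (1 - atom_fraction)
  }
  table[[element]] <- d
  table
}

#' Parse a chemical formula string
#'
#' Accepts the plain element-count syntax `C6H12O6`; a missing count means 1
#' and a repeated element accumulates. Parenthesised groups, charges and
#' isotope prefixes are not supported.
#'
#' @param text Formula string.
#' @param table Isotope table used to validate element symbols.
#' @return Named integer vector of element counts (class `chem_formula`).
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(text, table = default_iso_table()) {
  if (!is.character(text) || length(text) != 1 || is.na(text) ||
      !nzchar(text)) {
    stop("formula string is empty")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("cannot parse formula near: ", text)
  }
  els <- sub("[0-9]*$", "", toks)
  cnt <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
  cnt[is.na(cnt)] <- 1L
  bad <- setdiff(unique(els), names(table))
  if (length(bad)) stop("unknown element ", paste(bad, collapse = ", "))
  if (any(cnt <= 0)) {
    stop("zero count for ", paste(els[cnt <= 0], collapse = ", "))
  }
  out <- vapply(split(cnt, els), sum, integer(1))
  as_formula(out)
}

as_formula <- function(x) {
  stopifnot(length(x) >= 1, !is.null(names(x)), all(x >= 0), all(x == round(x)))
  x <- x[x > 0]
  if (!length(x)) stop("formula has no atoms")
  storage.mode(x) <- "integer"
  structure(x[order(names(x))], class = "chem_formula")
}

#' Add two formulas element-wise
#' @param a,b Named count vectors as returned by [parse_formula()].
#' @return Combined `chem_formula`.
#' @export
formula_add <- function(a, b) {
  els <- union(names(a), names(b))
  out <- setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  as_formula(out)
}

#' @export
format.chem_formula <- function(x, ...) {
  paste0(names(x), ifelse(x == 1L, "", x), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula>", format(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a formula
#'
#' The monoisotopic anchor is defined as the all-lightest-isotope composition
#' regardless of enrichment, which keeps envelope indexing stable across
#' enrichment levels.
#'
#' @inheritParams formula_masses
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("C6H12O6"))  # 180.063388
#' @export
monoisotopic_mass <- function(f, table = default_iso_table()) {
  formula_masses(f, table, what = "mono")
}

#' Abundance-weighted expected mass of a formula
#'
#' Sum over elements of count times the abundance-weighted mean isotope mass;
#' by linearity of expectation this equals the probability-weighted mean mass
#' of the full isotopologue distribution, so it serves as an independent
#' check on the simulators.
#'
#' @param f A `chem_formula`.
#' @param table An `iso_table` (possibly enriched).
#' @param what Internal.
#' @return Mass in Da.
#' @export
expected_mass <- function(f, table = default_iso_table()) {
  formula_masses(f, table, what = "mean")
}

formula_masses <- function(f, table, what = c("mono", "mean")) {
  what <- match.arg(what)
  miss <- setdiff(names(f), names(table))
  if (length(miss)) stop("element not in table: ", paste(miss, collapse = ", "))
  per <- vapply(names(f), function(el) {
    d <- table[[el]]
    if (what == "mono") d$mass[1] else sum(d$mass * d$abundance)
  }, numeric(1))
  sum(per * as.numeric(f))
}

PROTON_MASS <- 1.007276466

#' Convert a neutral mass to m/z for a (de)protonated ion
#'
#' Positive mode uses protonation `[M + zH]z+`, negative mode deprotonation
#' `[M - zH]z-`; the proton mass (1.007276466 Da) is used for the charge
#' carrier.
#'
#' @param neutral_mass Neutral monoisotopic (or any) mass in Da.
#' @param charge Positive integer charge magnitude.
#' @param polarity `"positive"` or `"negative"`.
#' @return m/z in Th.
#' @examples
#' mz_from_neutral(180.063388, 1, "negative")  # glucose [M-H]-
#' @export
mz_from_neutral <- function(neutral_mass, charge = 1L,
                            polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (any(charge < 1) || any(charge != round(charge))) {
    stop("charge must be a positive integer")
  }
  sgn <- if (polarity == "positive") 1 else -1
  mz <- (neutral_mass + sgn * charge * PROTON_MASS) / charge
  if (any(mz <= 0)) stop("resulting m/z is not positive")
  mz
}

#' Invert [mz_from_neutral()]
#' @inheritParams mz_from_neutral
#' @param mz m/z in Th.
#' @return Neutral mass in Da.
#' @export
mz_to_neutral <- function(mz, charge = 1L,
                          polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  sgn <- if (polarity == "positive") 1 else -1
  mz * charge - sgn * charge * PROTON_MASS
}
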