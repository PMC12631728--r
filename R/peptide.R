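residue_table <- function() {
  if (is.null(.isosip$residues)) {
    path <- system.file("extdata", "residues.tsv", package = "isosip",
                        mustWork = TRUE)
    raw <- utils::read.delim(path, stringsAsFactors = FALSE)
    .isosip$residues <- setNames(lapply(raw$formula, parse_formula), raw$code)
  }
  .isosip$residues
}

#' Elemental composition of an amino-acid residue
#'
#' Returns the dehydrated (residue) composition of one of the 20 canonical
#' amino acids; the peptide bond water is accounted for once per peptide via
#' the terminal groups.
#'
#' @param code One-letter residue code.
#' @return A `chem_formula`.
#' @examples
#' residue_formula("G")  # C2H3NO
#' @export
residue_formula <- function(code) {
  tab <- residue_table()
  f <- tab[[code]]
  if (is.null(f)) stop("unknown residue code: ", code)
  f
}

#' Elemental composition of a peptide
#'
#' Sum of residue compositions plus the terminal groups (defaults H at the
#' N-terminus and OH at the C-terminus, i.e. one water per peptide).
#'
#' @param sequence Peptide as a string of one-letter residue codes.
#' @param n_term,c_term Terminal-group formulas (strings or `chem_formula`).
#' @return A `chem_formula`.
#' @examples
#' peptide_formula("HYAHVDCPGHADYVK")
#' @export
peptide_formula <- function(sequence, n_term = "H", c_term = "HO") {
  res <- peptide_residues(sequence)
  f <- Reduce(formula_add, res)
  f <- formula_add(f, ensure_formula(n_term, default_iso_table()))
  formula_add(f, ensure_formula(c_term, default_iso_table()))
}

peptide_residues <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    stop("peptide sequence is empty")
  }
  codes <- strsplit(sequence, "")[[1]]
  lapply(codes, residue_formula)
}

#' Discrete convolution of two probability vectors
#'
#' Direct convolution; the output length is `length(a) + length(b) - 1` and
#' the total is the product of the input totals. This is the inner step of
#' the incremental peptide/fragment envelope builder, so calls are counted
#' (see [convolution_count()]).
#'
#' @param a,b Numeric probability vectors indexed from k = 0.
#' @return Numeric vector, their convolution.
#' @export
convolve_dist <- function(a, b) {
  .isosip$n_conv <- (.isosip$n_conv %||% 0L) + 1L
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (j in seq_along(b)) {
    if (b[j] != 0) {
      idx <- j:(j + length(a) - 1L)
      out[idx] <- out[idx] + a * b[j]
    }
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Convolution operation counter
#'
#' Diagnostics for the incremental fragment builder: the counter increments
#' on every [convolve_dist()] call, so tests can assert that all b-ion
#' envelopes of an n-residue peptide cost n - 1 convolutions rather than
#' O(n^2).
#'
#' @param reset If `TRUE`, zero the counter.
#' @return The current count, invisibly when resetting.
#' @export
convolution_count <- function(reset = FALSE) {
  if (reset) {
    .isosip$n_conv <- 0L
    return(invisible(0L))
  }
  .isosip$n_conv %||% 0L
}

# aggregate envelope of a formula by per-element FFT power (no sticks)
formula_neutron_dist <- function(f, table) {
  envelope_fft(f, table, trim = 0)$p
}

#' Precursor isotopic envelope of a peptide by residue convolution
#'
#' Builds each residue's aggregate extra-neutron distribution from the
#' (possibly enriched) isotope table, convolves them left to right, folds in
#' the terminal groups, and charges the result. The result is
#' indistinguishable (to ~1e-12 per index) from a single FFT envelope of the
#' whole peptide formula; the residue route is what makes incremental
#' fragment computation cheap.
#'
#' @inheritParams peptide_formula
#' @param table An `iso_table`.
#' @param ion An [ion_spec()]; peptides are positive-mode by convention.
#' @param as Return `"sticks"` (default) or the neutral `"envelope"`.
#' @return A stick-spectrum data frame (`mz`, `intensity`, base peak 100) or
#'   an `iso_envelope`.
#' @examples
#' precursor_envelope("PEPTIDE", ion = ion_spec(2))
#' @export
precursor_envelope <- function(sequence, table = default_iso_table(),
                               ion = ion_spec(1L, "positive"),
                               n_term = "H", c_term = "HO",
                               as = c("sticks", "envelope")) {
  as <- match.arg(as)
  res <- peptide_residues(sequence)
  p <- Reduce(convolve_dist, lapply(res, formula_neutron_dist, table = table))
  term <- formula_add(ensure_formula(n_term, table),
                      ensure_formula(c_term, table))
  p <- convolve_dist(p, formula_neutron_dist(term, table))
  env <- new_envelope(
    anchor_mass = monoisotopic_mass(peptide_formula(sequence, n_term, c_term),
                                    table),
    spacing = 1.003355, p = trim_tail(p),
    formula = peptide_formula(sequence, n_term, c_term))
  if (as == "envelope") env else envelope_to_sticks(env, ion)
}

trim_tail <- function(p, tol = 1e-10) {
  keep <- max(1L, suppressWarnings(max(which(p >= tol))))
  p[seq_len(keep)]
}

#' Isotopic envelopes of all b/y fragment ions of a peptide
#'
#' b ions are the N-terminal prefixes (neutral composition = sum of residues;
#' the proton is added at charging), y ions the C-terminal suffixes plus
#' water, which makes b_i / y_(n-i) complementarity exact: their neutral
#' formulas sum to the full peptide's. Prefix envelopes are built
#' incrementally (each b_i from b_(i-1) and one residue), and likewise the
#' suffixes, so the whole fragment set costs 2(n - 1) residue convolutions.
#'
#' @inheritParams precursor_envelope
#' @param charges Integer vector of fragment charge states (default 1:2).
#' @param min_relative Per-envelope stick pruning threshold on the 0-100
#'   relative scale (default 0.5).
#' @return A `fragment_set`: list of records with `series` ("b"/"y"),
#'   `index`, `charge`, `envelope` (`iso_envelope`) and `sticks`.
#' @examples
#' fr <- fragment_envelopes("PEPTIDE", charges = 1L)
#' @export
fragment_envelopes <- function(sequence, table = default_iso_table(),
                               charges = 1:2, min_relative = 0.5) {
  if (any(charges < 1)) stop("fragment charge must be >= 1")
  res <- peptide_residues(sequence)
  n <- length(res)
  if (n < 2) stop("peptide must have at least 2 residues for fragments")
  dists <- lapply(res, formula_neutron_dist, table = table)
  water <- formula_neutron_dist(parse_formula("H2O"), table)

  res_mono <- vapply(res, monoisotopic_mass, numeric(1), table = table)
  water_mono <- monoisotopic_mass(parse_formula("H2O"), table)

  out <- list()
  # b series: prefix accumulations
  acc <- dists[[1]]; mass <- res_mono[1]; fcur <- res[[1]]
  for (i in seq_len(n - 1)) {
    if (i > 1) {
      acc <- convolve_dist(acc, dists[[i]])
      mass <- mass + res_mono[i]
      fcur <- formula_add(fcur, res[[i]])
    }
    env <- new_envelope(mass, 1.003355, trim_tail(acc), formula = fcur)
    for (z in charges) {
      out[[length(out) + 1L]] <- fragment_record("b", i, z, env, min_relative)
    }
  }
  # y series: suffix accumulations, water folded in from the start
  acc <- convolve_dist(dists[[n]], water)
  mass <- res_mono[n] + water_mono
  fcur <- formula_add(res[[n]], parse_formula("H2O"))
  for (j in seq_len(n - 1)) {
    if (j > 1) {
      k <- n - j + 1L
      acc <- convolve_dist(acc, dists[[k]])
      mass <- mass + res_mono[k]
      fcur <- formula_add(fcur, res[[k]])
    }
    env <- new_envelope(mass, 1.003355, trim_tail(acc), formula = fcur)
    for (z in charges) {
      out[[length(out) + 1L]] <- fragment_record("y", j, z, env, min_relative)
    }
  }
  structure(out, class = "fragment_set", sequence = sequence)
}

fragment_record <- function(series, index, charge, env, min_relative) {
  sticks <- envelope_to_sticks(env, ion_spec(charge, "positive"),
                               min_relative = min_relative)
  list(series = series, index = index, charge = charge,
       envelope = env, sticks = sticks)
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("<fragment_set> ", attr(x, "sequence"), ": ", length(x),
      " fragment envelopes\n", sep = "")
  invisible(x)
}

#' Flatten a fragment set into a stick table
#'
#' @param x A `fragment_set`.
#' @param ... Unused.
#' @return Data frame with columns `series`, `index`, `charge`, `mz`,
#'   `relative_intensity`.
#' @export
as.data.frame.fragment_set <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    data.frame(series = r$series, index = r$index, charge = r$charge,
               mz = r$sticks$mz, relative_intensity = r$sticks$intensity,
               stringsAsFactors = FALSE)
  }))
}
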