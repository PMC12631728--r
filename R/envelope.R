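#' Per-element extra-neutron distribution raised to a convolution power
#'
#' The single-atom distribution over extra-neutron count k (k = nucleon
#' minus the lightest nucleon) is convolved with itself `count` times via
#' FFT: transform, pointwise power, inverse transform. Numerical ringing
#' below 1e-12 is clamped to zero.
#'
#' @param element Element symbol.
#' @param count Number of atoms (0 gives the convolution identity, a delta
#'   at k = 0).
#' @param table An `iso_table`.
#' @param length Grid length; defaults to the smallest power of two covering
#'   the maximal reachable k.
#' @return Numeric probability vector indexed by k = 0, 1, ...
#' @export
elemental_distribution <- function(element, count, table = default_iso_table(),
                                   length = NULL) {
  if (!element %in% names(table)) stop("unknown element ", element)
  count <- as.integer(count)
  if (is.na(count) || count < 0) stop("count must be a non-negative integer")
  d <- table[[element]]
  atom <- numeric(max(d$nucleon) - min(d$nucleon) + 1L)
  atom[d$nucleon - min(d$nucleon) + 1L] <- d$abundance
  if (count == 0) return(1)
  kmax <- (base::length(atom) - 1L) * count
  n <- if (is.null(length)) 2^ceiling(log2(kmax + 1)) else length
  if (n < kmax + 1) {
    warning("grid length ", n, " truncates the reachable range ", kmax + 1)
  }
  x <- c(atom, numeric(n - base::length(atom)))
  p <- Re(stats::fft(stats::fft(x)^count, inverse = TRUE)) / n
  p[abs(p) < 1e-12] <- 0
  p[seq_len(min(n, kmax + 1))]
}

new_envelope <- function(anchor_mass, spacing, p, formula = NULL) {
  stopifnot(all(p >= 0), length(p) >= 1)
  structure(list(anchor_mass = anchor_mass, spacing = spacing,
                 p = as.numeric(p), formula = formula),
            class = "iso_envelope")
}

#' Aggregate isotopic envelope of a formula by FFT convolution
#'
#' Computes the distribution of the total extra-neutron count of a molecule:
#' each element's single-atom distribution is Fourier-transformed, raised to
#' the power of its stoichiometric count, the transforms are multiplied
#' pointwise, and a single inverse FFT yields the aggregate envelope. Fine
#' structure is deliberately ignored; all isotopologues with the same total
#' neutron count collapse onto one peak.
#'
#' Aggregate peaks are placed at `anchor + k * spacing` where the anchor is
#' the monoisotopic (all-lightest) mass. The default spacing is the
#' 13C-12C mass difference because CHNOPS envelopes are carbon-dominated;
#' pass `spacing = "average"` to use the probability-weighted mean mass step
#' of the molecule instead.
#'
#' @inheritParams simulate_fine_structure
#' @param max_k Truncate the envelope at this extra-neutron count
#'   (default: the maximal reachable count). Truncation is never silent: a
#'   warning reports the probability mass lost.
#' @param spacing Da per extra neutron, or `"average"`.
#' @param trim Trailing probabilities below this are trimmed (default 1e-10).
#' @return An `iso_envelope`: list with `anchor_mass` (Da), `spacing` (Da),
#'   `p` (probability vector over k = 0..K) and `formula`.
#' @examples
#' env <- envelope_fft(parse_formula("C6H12O6"))
#' @export
envelope_fft <- function(f, table = default_iso_table(), max_k = NULL,
                         spacing = 1.003355, trim = 1e-10) {
  f <- ensure_formula(f, table)
  els <- names(f)
  kmax_total <- sum(vapply(els, function(el) {
    d <- table[[el]]
    (max(d$nucleon) - min(d$nucleon)) * f[[el]]
  }, numeric(1)))
  n <- 2^ceiling(log2(kmax_total + 1))
  acc <- rep(1 + 0i, n)
  for (el in els) {
    d <- table[[el]]
    atom <- numeric(n)
    atom[d$nucleon - min(d$nucleon) + 1L] <- d$abundance
    acc <- acc * stats::fft(atom)^f[[el]]
  }
  p <- Re(stats::fft(acc, inverse = TRUE)) / n
  p[abs(p) < 1e-12] <- 0
  p <- p[seq_len(kmax_total + 1)]
  if (!is.null(max_k) && max_k < kmax_total) {
    lost <- sum(p[(max_k + 2):length(p)])
    if (lost > 0) {
      warning("truncation at k = ", max_k, " drops probability ",
              signif(lost, 3))
    }
    p <- p[seq_len(max_k + 1)]
  }
  # trim trailing negligible entries (never the k = 0 anchor)
  keep <- max(1L, suppressWarnings(max(which(p >= trim))))
  p <- p[seq_len(keep)]
  if (identical(spacing, "average")) {
    spacing <- average_neutron_spacing(f, table)
  }
  new_envelope(anchor_mass = monoisotopic_mass(f, table),
               spacing = spacing, p = p, formula = f)
}

# probability-weighted mean mass increment per extra neutron
average_neutron_spacing <- function(f, table) {
  num <- 0; den <- 0
  for (el in names(f)) {
    d <- table[[el]]
    dk <- d$nucleon - d$nucleon[1]
    dm <- d$mass - d$mass[1]
    num <- num + f[[el]] * sum(d$abundance * dm)
    den <- den + f[[el]] * sum(d$abundance * dk)
  }
  if (den == 0) 1.003355 else num / den
}

#' @export
print.iso_envelope <- function(x, ...) {
  lab <- if (is.null(x$formula)) "" else paste0(" ", format(x$formula))
  cat("<iso_envelope>", lab, ": K = ", length(x$p) - 1,
      ", anchor ", round(x$anchor_mass, 6), " Da, spacing ",
      round(x$spacing, 6), " Da\n", sep = "")
  invisible(x)
}

#' Mean extra-neutron count of an envelope
#' @param env An `iso_envelope`.
#' @return Expected k (probability-weighted).
#' @export
envelope_mean <- function(env) {
  k <- seq_along(env$p) - 1
  sum(k * env$p) / sum(env$p)
}

#' Convert an aggregate envelope into a charged stick spectrum
#'
#' @param env An `iso_envelope`.
#' @param ion An [ion_spec()].
#' @param min_relative Drop sticks below this relative intensity (on the
#'   0-100 scale); default 0 keeps all.
#' @return A data frame with columns `mz` and `intensity`, intensities
#'   normalized so the base peak is 100.
#' @export
envelope_to_sticks <- function(env, ion = ion_spec(1L, "positive"),
                               min_relative = 0) {
  k <- seq_along(env$p) - 1
  mz <- mz_from_neutral(env$anchor_mass + k * env$spacing,
                        ion$charge, ion$polarity)
  intensity <- env$p / max(env$p) * 100
  keep <- intensity >= min_relative & env$p > 0
  data.frame(mz = mz[keep], intensity = intensity[keep])
}

#' Total-variation distance between two discrete spectra
#'
#' Utility used to compare simulated against exact fine structures: species
#' are aligned by composition (for `fine_spectrum`s) or by index, and the
#' distance is half the L1 difference of the probability vectors.
#'
#' @param a,b `fine_spectrum` objects or plain probability vectors.
#' @return Total-variation distance in `[0, 1]`.
#' @export
total_variation <- function(a, b) {
  if (inherits(a, "fine_spectrum") && inherits(b, "fine_spectrum")) {
    keys <- union(a$composition, b$composition)
    pa <- pb <- setNames(numeric(length(keys)), keys)
    pa[a$composition] <- a$probability
    pb[b$composition] <- b$probability
    sum(abs(pa - pb)) / 2
  } else {
    n <- max(length(a), length(b))
    pa <- c(a, numeric(n - length(a)))
    pb <- c(b, numeric(n - length(b)))
    sum(abs(pa - pb)) / 2
  }
}
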