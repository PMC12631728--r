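# A "theoretical set" is a list of stick-spectrum data frames, one per
# isotopic envelope (precursor and/or fragment ions). A single data frame is
# treated as a one-envelope set.
as_theoretical_set <- function(theoretical) {
  if (is.data.frame(theoretical)) list(theoretical)
  else if (inherits(theoretical, "fragment_set")) {
    lapply(theoretical, `[[`, "sticks")
  } else theoretical
}

combine_sticks <- function(theoretical) {
  ts <- as_theoretical_set(theoretical)
  do.call(rbind, lapply(ts, function(d) d[c("mz", "intensity")]))
}

#' Theoretical MS2 spectrum of a peptide-spectrum match
#'
#' Convenience builder for the scorers: the precursor envelope and/or all
#' b/y fragment envelopes of a peptide at the enrichment encoded in `table`.
#'
#' @inheritParams precursor_envelope
#' @param charge Precursor charge state.
#' @param fragment_charges Charge states for the b/y series.
#' @param include Which envelopes to include.
#' @param min_relative Per-envelope stick pruning threshold (0-100 scale).
#' @return A named list of stick-spectrum data frames.
#' @export
theoretical_psm <- function(sequence, table = default_iso_table(),
                            charge = 2L, fragment_charges = 1:2,
                            include = c("both", "precursor", "fragments"),
                            min_relative = 0.5) {
  include <- match.arg(include)
  out <- list()
  if (include != "fragments") {
    env <- precursor_envelope(sequence, table, as = "envelope")
    sticks <- envelope_to_sticks(env, ion_spec(charge, "positive"),
                                 min_relative = min_relative)
    out$precursor <- sticks
  }
  if (include != "precursor") {
    fr <- fragment_envelopes(sequence, table, charges = fragment_charges,
                             min_relative = min_relative)
    for (r in fr) {
      out[[paste0(r$series, r$index, "_z", r$charge)]] <- r$sticks
    }
  }
  out
}

#' Weighted dot product score
#'
#' For each isotopic envelope, the matched observed intensities are compared
#' to the theoretical stick intensities with a cosine normalization against
#' the self-product of the *full* theoretical envelope: a complete,
#' perfectly proportional match scores 1 per envelope and any missing stick
#' strictly lowers the score. The total is the sum over envelopes, so every
#' stick of every isotopic envelope contributes. The score is what makes
#' enrichment profiles sharply peaked: it rewards matching the *shape* of
#' each isotopic envelope, not merely hitting its m/z positions.
#'
#' Observed intensities enter linearly by default; `transform = "sqrt"`
#' applies a square-root variance stabilization first (this flattens
#' envelope shapes and widens enrichment profiles, so it is not the
#' default).
#'
#' @param theoretical A theoretical set (see [theoretical_psm()]), a single
#'   stick data frame, or a `fragment_set`.
#' @param observed An `ms_spectrum`.
#' @param tolerance Match tolerance in Da.
#' @param normalize If `FALSE`, return the raw weighted dot product
#'   `sum(t * u)` (with `u` the transformed observed intensities) without
#'   the cosine normalization.
#' @param transform Observed-intensity transform, `"linear"` or `"sqrt"`.
#' @return Non-negative score.
#' @export
score_wdp <- function(theoretical, observed, tolerance = 0.01,
                      normalize = TRUE,
                      transform = c("linear", "sqrt")) {
  transform <- match.arg(transform)
  ts <- as_theoretical_set(theoretical)
  omz <- observed$mz; oint <- observed$intensity
  total <- 0
  for (d in ts) {
    hit <- nearest_peak_index(d$mz, omz, oint, tolerance)
    m <- hit > 0
    if (!any(m)) next
    u <- oint[hit[m]]
    if (transform == "sqrt") u <- sqrt(u)
    t <- d$intensity[m]
    if (normalize) {
      denom <- sqrt(sum(d$intensity^2) * sum(u^2))
      if (denom > 0) total <- total + sum(t * u) / denom
    } else {
      total <- total + sum(t * u)
    }
  }
  total
}

# --- XCorr -----------------------------------------------------------------

# SEQUEST-style observed preprocessing: sqrt intensities, 10 m/z regions
# each normalized to max 50, binned, then background-corrected so that the
# final score is dot(theo, corrected) = dot0 - mean of the +-offset dots.
xcorr_prepare <- function(observed, bin_width = 1.0005079,
                          offset_range = 75L, mz_max = NULL) {
  mz <- observed$mz
  intensity <- sqrt(observed$intensity)
  if (length(mz)) {
    breaks <- seq(min(mz), max(mz), length.out = 11)
    region <- findInterval(mz, breaks, rightmost.closed = TRUE,
                           all.inside = TRUE)
    for (r in unique(region)) {
      i <- region == r
      m <- max(intensity[i])
      if (m > 0) intensity[i] <- intensity[i] / m * 50
    }
  }
  n_bins <- ceiling((if (is.null(mz_max)) max(mz, 1) else mz_max) /
                      bin_width) + offset_range + 1L
  vec <- numeric(n_bins)
  idx <- pmin(floor(mz / bin_width) + 1L, n_bins)
  for (k in seq_along(idx)) vec[idx[k]] <- max(vec[idx[k]], intensity[k])
  # moving-sum background over +-offset_range bins, excluding the centre
  w <- 2L * offset_range + 1L
  pad <- c(numeric(offset_range), vec, numeric(offset_range))
  ms <- cumsum(pad)
  ms <- c(ms[w], diff(ms, lag = w))
  corrected <- vec - (ms - vec) / (w - 1L)
  list(corrected = corrected, bin_width = bin_width, n_bins = n_bins)
}

theo_bins <- function(theoretical, bin_width, n_bins) {
  d <- combine_sticks(theoretical)
  idx <- pmin(floor(d$mz / bin_width) + 1L, n_bins)
  agg <- tapply(d$intensity, idx, max)
  list(idx = as.integer(names(agg)), w = as.numeric(agg))
}

#' Cross-correlation score
#'
#' SEQUEST-style XCorr: both spectra are binned (default 1.0005079 Da, the
#' averagine-scaled nominal mass step); the observed spectrum is
#' square-rooted and normalized to a maximum of 50 in each of 10 m/z
#' regions; the score is the dot product at zero offset minus the mean dot
#' product over offsets within +-`offset_range` bins, computed with the
#' fast single-pass background-subtraction identity.
#'
#' @inheritParams score_wdp
#' @param bin_width Bin width in Da.
#' @param offset_range Background offsets, in bins, on each side.
#' @return Score (unbounded; positive means above-background correlation).
#' @export
score_xcorr <- function(theoretical, observed, bin_width = 1.0005079,
                        offset_range = 75L) {
  theo <- combine_sticks(theoretical)
  mz_max <- max(c(observed$mz, theo$mz, 1))
  prep <- xcorr_prepare(observed, bin_width, offset_range, mz_max = mz_max)
  tb <- theo_bins(theo, bin_width, prep$n_bins)
  sum(tb$w * prep$corrected[tb$idx]) / 1e4
}

# --- MVH -------------------------------------------------------------------

#' Multivariate hypergeometric score
#'
#' MyriMatch-style MVH: observed peaks are ranked into `n_classes` equal-
#' count intensity classes; matching the theoretical sticks against the
#' observed peaks then gives a per-class match count, and the score is
#' -ln of the multivariate hypergeometric probability of drawing those
#' counts when the sticks sample bins at random from the candidate m/z bins
#' (peak bins of each class plus empty bins).
#'
#' @inheritParams score_wdp
#' @param n_classes Number of intensity classes (default 3).
#' @param n_bins Total number of candidate m/z bins; default is the observed
#'   m/z span divided by `2 * tolerance` (each bin one tolerance window),
#'   floored so the draw is always feasible.
#' @return Non-negative score; 0 when there are no theoretical sticks.
#' @export
score_mvh <- function(theoretical, observed, tolerance = 0.01,
                      n_classes = 3L, n_bins = NULL) {
  theo <- combine_sticks(theoretical)
  n <- nrow(theo)
  if (n == 0) return(0)
  omz <- observed$mz; oint <- observed$intensity
  K_tot <- length(omz)
  if (K_tot == 0) return(0)
  n_classes <- min(n_classes, K_tot)
  # class 1 = most intense; equal-count classes by intensity rank
  cls <- ceiling(rank(-oint, ties.method = "first") / K_tot * n_classes)
  K <- tabulate(cls, nbins = n_classes)
  hit <- nearest_peak_index(theo$mz, omz, oint, tolerance)
  matched <- unique(hit[hit > 0])
  x <- tabulate(cls[matched], nbins = n_classes)
  x_tot <- sum(x)
  if (is.null(n_bins)) {
    span <- max(omz) - min(omz)
    n_bins <- max(ceiling(span / (2 * tolerance)), K_tot + (n - x_tot))
  }
  if (n_bins < K_tot + (n - x_tot)) {
    stop("n_bins too small for the observed peaks and unmatched sticks")
  }
  lp <- sum(lchoose(K, x)) + lchoose(n_bins - K_tot, n - x_tot) -
    lchoose(n_bins, n)
  max(0, -lp)
}

# --- spectral entropy ------------------------------------------------------

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Spectral entropy similarity
#'
#' Peaks of the two spectra are aligned on a common grid (greedy clustering
#' of the pooled m/z list with gaps below the tolerance merged), each
#' spectrum is normalized to total intensity 1, and the similarity is
#' `1 - (2 * S_AB - S_A - S_B) / ln(4)` where `S_AB` is the Shannon entropy
#' of the half-and-half mixture. Identical spectra score 1; spectra with
#' disjoint support score 0.
#'
#' @param a,b `ms_spectrum` objects or stick data frames (`mz`, `intensity`).
#' @param tolerance Alignment tolerance in Da.
#' @return Similarity in `[0, 1]`.
#' @export
entropy_similarity <- function(a, b, tolerance = 0.01) {
  pk <- function(x) {
    if (is.data.frame(x)) list(mz = x$mz, intensity = x$intensity)
    else list(mz = x$mz, intensity = x$intensity)
  }
  a <- pk(a); b <- pk(b)
  if (!length(a$mz) || !length(b$mz)) return(0)
  mz <- c(a$mz, b$mz)
  src <- rep(1:2, c(length(a$mz), length(b$mz)))
  int <- c(a$intensity / sum(a$intensity), b$intensity / sum(b$intensity))
  o <- order(mz)
  mz <- mz[o]; src <- src[o]; int <- int[o]
  cl <- cumsum(c(TRUE, diff(mz) > tolerance))
  pa <- tapply(ifelse(src == 1, int, 0), cl, sum)
  pb <- tapply(ifelse(src == 2, int, 0), cl, sum)
  s_a <- shannon(as.numeric(pa))
  s_b <- shannon(as.numeric(pb))
  s_ab <- shannon(as.numeric(pa + pb) / 2)
  sim <- 1 - (2 * s_ab - s_a - s_b) / log(4)
  min(1, max(0, sim))
}
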