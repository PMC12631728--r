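#' Construct a centroided spectrum
#'
#' The common container for observed and simulated scans: a sorted peak list
#' plus scan metadata. Peaks are re-sorted by m/z on construction and
#' negative intensities are rejected.
#'
#' @param mz Numeric vector of peak m/z values (Th).
#' @param intensity Numeric vector of peak intensities (arbitrary units).
#' @param scan Scan number.
#' @param ms_level 1 or 2.
#' @param rt Retention time in minutes (the canonical unit throughout).
#' @param precursor_mz Precursor m/z for data-dependent MS2 scans.
#' @param charge Precursor charge, if known.
#' @param extra Named list of additional metadata fields, preserved verbatim
#'   by the readers/writers.
#' @return An object of class `ms_spectrum`.
#' @export
new_spectrum <- function(mz, intensity, scan = NA_integer_, ms_level = 2L,
                         rt = NA_real_, precursor_mz = NULL, charge = NULL,
                         extra = list()) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("negative peak intensity")
  o <- order(mz)
  structure(list(mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
                 scan = as.integer(scan), ms_level = as.integer(ms_level),
                 rt = as.numeric(rt),
                 precursor_mz = if (is.null(precursor_mz)) NA_real_
                                else as.numeric(precursor_mz),
                 charge = if (is.null(charge)) NA_integer_
                          else as.integer(charge),
                 extra = extra),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat("<ms_spectrum> scan ", x$scan, " (MS", x$ms_level, "), ",
      length(x$mz), " peaks",
      if (!is.na(x$rt)) paste0(", RT ", round(x$rt, 3), " min"),
      if (!is.na(x$precursor_mz)) paste0(", precursor m/z ",
                                         round(x$precursor_mz, 4)),
      "\n", sep = "")
  invisible(x)
}

#' Windowed top-N denoising of a spectrum
#'
#' Keeps a peak only if it ranks among the `top_n` most intense peaks within
#' the m/z window centred on it. This removes a dense stochastic noise floor
#' while keeping locally dominant signal peaks, and is deterministic.
#'
#' @param s An `ms_spectrum`.
#' @param window Window width in Da (default 100).
#' @param top_n Peaks retained per window (default 10).
#' @return The filtered `ms_spectrum`.
#' @export
denoise <- function(s, window = 100, top_n = 10L) {
  stopifnot(inherits(s, "ms_spectrum"))
  n <- length(s$mz)
  if (n == 0) return(s)
  lo <- findInterval(s$mz - window / 2, s$mz, left.open = TRUE) + 1L
  hi <- findInterval(s$mz + window / 2, s$mz)
  keep <- logical(n)
  for (i in seq_len(n)) {
    neigh <- s$intensity[lo[i]:hi[i]]
    keep[i] <- sum(neigh > s$intensity[i]) < top_n
  }
  s$mz <- s$mz[keep]
  s$intensity <- s$intensity[keep]
  s
}

#' Match theoretical sticks against observed peaks
#'
#' Greedy assignment in descending theoretical intensity: each stick claims
#' the most intense not-yet-claimed observed peak within the tolerance, ties
#' broken by smallest absolute m/z error. Each observed peak is used at most
#' once.
#'
#' @param theoretical Stick-spectrum data frame (`mz`, `intensity`).
#' @param observed An `ms_spectrum`.
#' @param tolerance Match tolerance; Da by default, parts-per-million when
#'   `ppm = TRUE`.
#' @param ppm Interpret `tolerance` as ppm of the stick m/z.
#' @return A `match_result`: data frame `pairs` (columns `theo`, `obs`,
#'   `mz_error`), plus integer vectors `unmatched_theo`, `unmatched_obs`.
#' @export
match_peaks <- function(theoretical, observed, tolerance = 0.01,
                        ppm = FALSE) {
  stopifnot(inherits(observed, "ms_spectrum"))
  tmz <- theoretical$mz
  tint <- theoretical$intensity
  omz <- observed$mz
  oint <- observed$intensity
  tol <- if (ppm) tmz * tolerance * 1e-6 else rep(tolerance, length(tmz))
  lo <- findInterval(tmz - tol, omz, left.open = TRUE) + 1L
  hi <- findInterval(tmz + tol, omz)
  used <- logical(length(omz))
  theo_idx <- obs_idx <- integer(0)
  for (i in order(tint, decreasing = TRUE)) {
    if (lo[i] > hi[i]) next
    cand <- lo[i]:hi[i]
    cand <- cand[!used[cand]]
    if (!length(cand)) next
    best <- cand[oint[cand] == max(oint[cand])]
    if (length(best) > 1) best <- best[which.min(abs(omz[best] - tmz[i]))]
    used[best] <- TRUE
    theo_idx <- c(theo_idx, i)
    obs_idx <- c(obs_idx, best)
  }
  o <- order(theo_idx)
  structure(list(
    pairs = data.frame(theo = theo_idx[o], obs = obs_idx[o],
                       mz_error = omz[obs_idx[o]] - tmz[theo_idx[o]]),
    unmatched_theo = setdiff(seq_along(tmz), theo_idx),
    unmatched_obs = which(!used)),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", nrow(x$pairs), " matched, ",
      length(x$unmatched_theo), " theoretical and ",
      length(x$unmatched_obs), " observed unmatched\n", sep = "")
  invisible(x)
}

# fast non-exclusive matcher used inside the scorers' hot loops:
# for each stick, index of the most intense observed peak within tolerance
# (0 when none). Sticks are usually >= one neutron spacing apart, so peak
# reuse is not a practical concern at the default 0.01 Da tolerance.
nearest_peak_index <- function(tmz, omz, oint, tolerance) {
  lo <- findInterval(tmz - tolerance, omz, left.open = TRUE) + 1L
  hi <- findInterval(tmz + tolerance, omz)
  best <- integer(length(tmz))
  bint <- rep(-Inf, length(tmz))
  width <- max(0L, max(hi - lo, -1L) + 1L)
  if (width > 0) {
    for (j in 0:(width - 1L)) {
      idx <- lo + j
      ok <- idx <= hi
      if (!any(ok)) next
      cand_int <- rep(-Inf, length(tmz))
      cand_int[ok] <- oint[idx[ok]]
      better <- cand_int > bint
      best[better] <- idx[better]
      bint[better] <- cand_int[better]
    }
  }
  best
}
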