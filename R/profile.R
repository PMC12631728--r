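#' Theoretical spectra across an enrichment grid
#'
#' Precomputes the theoretical PSM spectrum of a peptide at every grid point
#' of an atom-fraction grid. Factored out of [score_profile()] so that many
#' observed spectra (e.g. replicate fixtures) can be profiled against one
#' precomputed grid.
#'
#' @inheritParams theoretical_psm
#' @param grid Vector of atom fractions in `[0, 1]`, strictly increasing.
#' @param element,nucleon The enriched isotope (default 13C).
#' @param base_table Isotope table before enrichment.
#' @return List (one entry per grid point) of theoretical sets.
#' @export
theoretical_grid <- function(sequence, grid = seq(0, 1, by = 0.01),
                             element = "C", nucleon = 13L,
                             base_table = default_iso_table(),
                             charge = 2L, fragment_charges = 1:2,
                             include = c("both", "precursor", "fragments"),
                             min_relative = 0.5) {
  include <- match.arg(include)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be increasing")
  lapply(grid, function(g) {
    tab <- apply_enrichment(base_table, element, nucleon, g)
    theoretical_psm(sequence, tab, charge = charge,
                    fragment_charges = fragment_charges, include = include,
                    min_relative = min_relative)
  })
}

#' Score a PSM across an enrichment grid
#'
#' Regenerates the theoretical precursor/fragment spectra of the peptide at
#' each grid enrichment and scores them against the observed spectrum with
#' each requested scoring function. The result is the score-vs-enrichment
#' curve from which the enrichment level is read off.
#'
#' @inheritParams theoretical_grid
#' @param observed An `ms_spectrum`.
#' @param scorers Subset of `c("wdp", "xcorr", "mvh", "entropy")`.
#' @param tolerance Match tolerance in Da (WDP/MVH/entropy).
#' @param theo_grid Optional precomputed [theoretical_grid()] (must match
#'   `grid`).
#' @return A `score_profile`: list with `grid` and `scores` (matrix, one
#'   column per scorer).
#' @export
score_profile <- function(sequence, observed, grid = seq(0, 1, by = 0.01),
                          element = "C", nucleon = 13L,
                          base_table = default_iso_table(),
                          scorers = c("wdp", "xcorr", "mvh", "entropy"),
                          charge = 2L, fragment_charges = 1:2,
                          include = c("both", "precursor", "fragments"),
                          tolerance = 0.01, theo_grid = NULL) {
  include <- match.arg(include)
  scorers <- match.arg(scorers, several.ok = TRUE)
  if (is.null(theo_grid)) {
    theo_grid <- theoretical_grid(sequence, grid, element, nucleon,
                                  base_table, charge, fragment_charges,
                                  include)
  }
  stopifnot(length(theo_grid) == length(grid))
  scores <- matrix(NA_real_, length(grid), length(scorers),
                   dimnames = list(NULL, scorers))
  prep <- NULL
  if ("xcorr" %in% scorers) {
    mz_max <- max(c(observed$mz,
                    vapply(theo_grid, function(ts) {
                      max(vapply(ts, function(d) max(d$mz, 0), numeric(1)))
                    }, numeric(1)), 1))
    prep <- xcorr_prepare(observed, mz_max = mz_max)
  }
  for (i in seq_along(grid)) {
    ts <- theo_grid[[i]]
    if ("wdp" %in% scorers) {
      scores[i, "wdp"] <- score_wdp(ts, observed, tolerance)
    }
    if ("xcorr" %in% scorers) {
      tb <- theo_bins(ts, prep$bin_width, prep$n_bins)
      scores[i, "xcorr"] <- sum(tb$w * prep$corrected[tb$idx]) / 1e4
    }
    if ("mvh" %in% scorers) {
      scores[i, "mvh"] <- score_mvh(ts, observed, tolerance)
    }
    if ("entropy" %in% scorers) {
      scores[i, "entropy"] <- entropy_similarity(combine_sticks(ts),
                                                 observed, tolerance)
    }
  }
  structure(list(grid = grid, scores = scores, sequence = sequence,
                 element = element, nucleon = nucleon),
            class = "score_profile")
}

#' @export
print.score_profile <- function(x, ...) {
  cat("<score_profile> ", x$sequence, ", ", length(x$grid),
      " grid points, scorers: ", paste(colnames(x$scores), collapse = ", "),
      "\n", sep = "")
  for (s in colnames(x$scores)) {
    est <- estimate_enrichment(x, s)
    cat(sprintf("  %-8s argmax %s  FWHM %s\n", s,
                format(est$estimate), format(est$fwhm)))
  }
  invisible(x)
}

#' Point estimate of enrichment and profile peak width
#'
#' The point estimate is the grid argmax of the chosen scorer (ties resolved
#' to the lowest fraction). The peak width is the full width at half maximum
#' of the min-max-normalized score curve, found by linear interpolation
#' between grid points; a flat profile yields `NA` for both.
#'
#' @param profile A `score_profile`.
#' @param scorer Column name of the scorer to use (default `"wdp"`).
#' @return List with `estimate` and `fwhm` (both atom fractions).
#' @export
estimate_enrichment <- function(profile, scorer = "wdp") {
  stopifnot(inherits(profile, "score_profile"))
  s <- profile$scores[, scorer]
  g <- profile$grid
  if (all(!is.finite(s)) || diff(range(s, finite = TRUE)) == 0) {
    return(list(estimate = NA_real_, fwhm = NA_real_))
  }
  z <- (s - min(s)) / (max(s) - min(s))
  m <- which.max(z)   # first maximum = lowest fraction on ties
  half_cross <- function(side) {
    if (side == "left") {
      below <- which(z[seq_len(m)] < 0.5)
      if (!length(below)) return(g[1])
      i <- max(below)
      g[i] + (0.5 - z[i]) / (z[i + 1] - z[i]) * (g[i + 1] - g[i])
    } else {
      idx <- m:length(z)
      below <- which(z[idx] < 0.5)
      if (!length(below)) return(g[length(g)])
      i <- idx[min(below)]
      g[i - 1] + (z[i - 1] - 0.5) / (z[i - 1] - z[i]) * (g[i] - g[i - 1])
    }
  }
  list(estimate = g[m], fwhm = half_cross("right") - half_cross("left"))
}

#' Estimate the isotopic enrichment of a peptide-spectrum match
#'
#' The estimator front-end: profiles the PSM score across the enrichment
#' grid for each requested scoring function and reads off the argmax
#' enrichment and profile peak width per scorer. Returns a fitted-model
#' object with the usual methods (`print`, `summary`, `coef`, `plot`).
#'
#' @inheritParams score_profile
#' @param spectrum The observed `ms_spectrum`.
#' @return An object of class `enrich_fit` with components `profile`
#'   (the `score_profile`), `estimates` (data frame: scorer, estimate,
#'   fwhm), and the call.
#' @examples
#' \dontrun{
#' fit <- fit_enrichment("HYAHVDCPGHADYVK", spec, charge = 3)
#' coef(fit)
#' }
#' @export
fit_enrichment <- function(sequence, spectrum, grid = seq(0, 1, by = 0.01),
                           element = "C", nucleon = 13L,
                           scorers = c("wdp", "xcorr", "mvh", "entropy"),
                           charge = 2L, fragment_charges = 1:2,
                           include = c("both", "precursor", "fragments"),
                           tolerance = 0.01,
                           base_table = default_iso_table(),
                           theo_grid = NULL) {
  include <- match.arg(include)
  prof <- score_profile(sequence, spectrum, grid, element, nucleon,
                        base_table, scorers, charge, fragment_charges,
                        include, tolerance, theo_grid)
  est <- do.call(rbind, lapply(colnames(prof$scores), function(s) {
    e <- estimate_enrichment(prof, s)
    data.frame(scorer = s, estimate = e$estimate, fwhm = e$fwhm,
               stringsAsFactors = FALSE)
  }))
  structure(list(profile = prof, estimates = est, sequence = sequence,
                 element = element, nucleon = nucleon,
                 call = match.call()),
            class = "enrich_fit")
}

#' @export
print.enrich_fit <- function(x, ...) {
  cat("Enrichment fit for ", x$sequence, " (", x$nucleon, x$element, ")\n",
      sep = "")
  best <- x$estimates[1, ]
  cat("  estimate (", best$scorer, "): ",
      sprintf("%.1f atom %%", 100 * best$estimate), "\n", sep = "")
  invisible(x)
}

#' @export
summary.enrich_fit <- function(object, ...) {
  cat("Enrichment fit: ", object$sequence, ", enriched isotope ",
      object$nucleon, object$element, "\n",
      "Grid: ", length(object$profile$grid), " points in [",
      min(object$profile$grid), ", ", max(object$profile$grid), "]\n\n",
      sep = "")
  est <- object$estimates
  est$estimate_pct <- 100 * est$estimate
  est$fwhm_pct <- 100 * est$fwhm
  print(est[c("scorer", "estimate_pct", "fwhm_pct")], row.names = FALSE)
  invisible(object)
}

#' @export
coef.enrich_fit <- function(object, ...) {
  setNames(object$estimates$estimate, object$estimates$scorer)
}

#' @export
plot.enrich_fit <- function(x, scorers = colnames(x$profile$scores), ...) {
  prof <- x$profile
  z <- prof$scores[, scorers, drop = FALSE]
  z <- apply(z, 2, function(v) {
    r <- range(v, finite = TRUE)
    if (diff(r) == 0) v * 0 else (v - r[1]) / diff(r)
  })
  graphics::matplot(prof$grid * 100, z, type = "l", lty = 1,
                    col = seq_len(ncol(z)),
                    xlab = "atom % enrichment",
                    ylab = "normalized score", ...)
  graphics::legend("topright", legend = colnames(z), lty = 1,
                   col = seq_len(ncol(z)), bty = "n")
  invisible(x)
}
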