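#' Noise model for synthetic observed spectra
#'
#' Defines how a clean theoretical stick spectrum is degraded into a
#' realistic centroided scan: Gaussian m/z jitter and lognormal intensity
#' jitter on the true sticks (lognormal keeps intensities positive), plus a
#' floor of random noise peaks. The defaults emulate a well-calibrated FTMS
#' instrument: 0.002 Da m/z jitter, 20 % intensity CV, 200 uniform noise
#' peaks at a signal-to-noise ratio of 10 relative to the base peak.
#'
#' @param n_noise_peaks Number of noise peaks added.
#' @param mz_range Noise m/z range; `NULL` spans the stick range +- 50 Th.
#' @param intensity_distribution `"uniform"` or `"exponential"` noise
#'   intensities.
#' @param snr Base-peak intensity divided by the noise intensity scale.
#' @param peak_mz_sigma Gaussian sd of stick m/z jitter, Da.
#' @param intensity_cv Coefficient of variation of stick intensity jitter.
#' @return A `noise_model` list.
#' @export
noise_model <- function(n_noise_peaks = 200L, mz_range = NULL,
                        intensity_distribution = c("uniform", "exponential"),
                        snr = 10, peak_mz_sigma = 0.002,
                        intensity_cv = 0.2) {
  intensity_distribution <- match.arg(intensity_distribution)
  stopifnot(n_noise_peaks >= 0, snr > 0, peak_mz_sigma >= 0,
            intensity_cv >= 0)
  structure(list(n_noise_peaks = as.integer(n_noise_peaks),
                 mz_range = mz_range,
                 intensity_distribution = intensity_distribution,
                 snr = snr, peak_mz_sigma = peak_mz_sigma,
                 intensity_cv = intensity_cv),
            class = "noise_model")
}

#' Degrade a theoretical stick spectrum into a synthetic observed scan
#'
#' @param theoretical Stick-spectrum data frame or theoretical set (see
#'   [theoretical_psm()]); sets are flattened.
#' @param nm A [noise_model()].
#' @param seed Integer seed (required; output is bit-identical per seed).
#' @param scan,rt,precursor_mz,charge Metadata for the synthetic scan.
#' @return An `ms_spectrum`.
#' @export
make_observed <- function(theoretical, nm = noise_model(), seed,
                          scan = 1L, rt = 30, precursor_mz = NULL,
                          charge = NULL) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  d <- combine_sticks(theoretical)
  with_seed(seed, {
    mz <- d$mz + stats::rnorm(nrow(d), 0, nm$peak_mz_sigma)
    if (nm$intensity_cv > 0) {
      sdlog <- sqrt(log(1 + nm$intensity_cv^2))
      fac <- stats::rlnorm(nrow(d), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      fac <- rep(1, nrow(d))
    }
    intensity <- d$intensity * fac
    if (nm$n_noise_peaks > 0) {
      rng <- if (is.null(nm$mz_range)) {
        c(max(0, min(d$mz) - 50), max(d$mz) + 50)
      } else nm$mz_range
      nmz <- stats::runif(nm$n_noise_peaks, rng[1], rng[2])
      scale <- max(d$intensity) / nm$snr
      nint <- switch(nm$intensity_distribution,
                     uniform = stats::runif(nm$n_noise_peaks, 0, scale),
                     exponential = stats::rexp(nm$n_noise_peaks, 1 / scale))
      mz <- c(mz, nmz)
      intensity <- c(intensity, nint)
    }
    new_spectrum(mz, intensity, scan = scan, ms_level = 2L, rt = rt,
                 precursor_mz = precursor_mz, charge = charge)
  })
}

#' Simulate a data-dependent LC-MS/MS run
#'
#' A minimal DDA cycle for exercising run summaries and the file writers:
#' each MS1 scan carries random peaks and is followed by `n_ms2_per_ms1`
#' MS2 scans whose precursors are the most intense peaks of that MS1 scan;
#' retention times increase monotonically across the gradient.
#'
#' @param n_ms1 Number of MS1 scans.
#' @param n_ms2_per_ms1 MS2 scans triggered per MS1 scan.
#' @param gradient_minutes Total run length in minutes.
#' @param seed Integer seed.
#' @param n_peaks_ms1 Peaks per MS1 scan.
#' @return List of `ms_spectrum` in acquisition order.
#' @export
make_run <- function(n_ms1 = 10L, n_ms2_per_ms1 = 4L, gradient_minutes = 10,
                     seed, n_peaks_ms1 = 50L) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(n_ms1 >= 1, n_ms2_per_ms1 >= 0, n_peaks_ms1 > n_ms2_per_ms1)
  with_seed(seed, {
    total <- n_ms1 * (1L + n_ms2_per_ms1)
    rts <- sort(stats::runif(total, 0, gradient_minutes))
    out <- vector("list", total)
    scan <- 0L
    pos <- 0L
    for (i in seq_len(n_ms1)) {
      scan <- scan + 1L; pos <- pos + 1L
      mz1 <- sort(stats::runif(n_peaks_ms1, 300, 1500))
      int1 <- stats::rexp(n_peaks_ms1, 1 / 1e6)
      out[[pos]] <- new_spectrum(mz1, int1, scan = scan, ms_level = 1L,
                                 rt = rts[pos])
      top <- order(int1, decreasing = TRUE)[seq_len(n_ms2_per_ms1)]
      for (j in seq_len(n_ms2_per_ms1)) {
        scan <- scan + 1L; pos <- pos + 1L
        nf <- 30L
        out[[pos]] <- new_spectrum(
          sort(stats::runif(nf, 100, mz1[top[j]] * 2)),
          stats::rexp(nf, 1 / 1e4),
          scan = scan, ms_level = 2L, rt = rts[pos],
          precursor_mz = mz1[top[j]],
          charge = sample(2:3, 1))
      }
    }
    out
  })
}

#' Write a complete synthetic PSM fixture to disk
#'
#' Emits an MGF file, an FT2 file and a JSON truth record (peptide, charge,
#' enrichment, seed, noise parameters) for a peptide observed at a given
#' enrichment, so downstream scoring can be exercised end to end with no
#' external data.
#'
#' @inheritParams make_observed
#' @param sequence Peptide sequence.
#' @param enrichment 13C atom fraction used to generate the spectrum.
#' @param charge Precursor charge.
#' @param dir Output directory.
#' @return Named list of the file paths written.
#' @export
write_fixture <- function(sequence, enrichment, charge = 2L,
                          nm = noise_model(), seed, dir = ".") {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  tab <- apply_enrichment(default_iso_table(), "C", 13, enrichment)
  theo <- theoretical_psm(sequence, tab, charge = charge)
  prec_mz <- mz_from_neutral(monoisotopic_mass(peptide_formula(sequence),
                                               tab), charge)
  obs <- make_observed(theo, nm, seed, precursor_mz = prec_mz,
                       charge = charge)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(mgf = file.path(dir, "fixture.mgf"),
                ft2 = file.path(dir, "fixture.ft2"),
                truth = file.path(dir, "truth.json"))
  write_mgf(obs, paths$mgf)
  write_ft2(obs, paths$ft2)
  truth <- list(sequence = sequence, enrichment = enrichment,
                charge = charge, seed = seed,
                noise = unclass(nm))
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, null = "null"),
             paths$truth)
  paths
}
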