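open_device <- function(path, width = 9, height = 5) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(path, width = width, height = height),
         svg = grDevices::svg(path, width = width, height = height),
         stop("unsupported image format: ", ext))
}

#' Mirror plot of a peptide-spectrum match
#'
#' Theoretical isotopic sticks are drawn upward and the observed spectrum
#' downward; observed peaks claimed by the match are highlighted and
#' unmatched observed peaks drawn in gray. Fragment envelopes can be
#' annotated with their series/index/charge labels.
#'
#' @param theoretical A theoretical set (see [theoretical_psm()]) or stick
#'   data frame.
#' @param observed An `ms_spectrum`.
#' @param match Optional `match_result` from [match_peaks()] computed on
#'   the flattened theoretical set; computed internally when `NULL`.
#' @param out_path Image file to write (`.png`, `.pdf` or `.svg`).
#' @param annotate Draw fragment labels.
#' @param tolerance Match tolerance used when `match` is `NULL`.
#' @param colors Named list with `theoretical`, `matched`, `unmatched`.
#' @return Invisibly, the plot's data layers: `theoretical`, `observed`
#'   (with a `matched` flag) and `labels`.
#' @export
mirror_plot <- function(theoretical, observed, match = NULL, out_path,
                        annotate = TRUE, tolerance = 0.01,
                        colors = list(theoretical = "goldenrod2",
                                      matched = "firebrick2",
                                      unmatched = "gray60")) {
  ts <- as_theoretical_set(theoretical)
  flat <- combine_sticks(ts)
  if (is.null(match)) match <- match_peaks(flat, observed, tolerance)
  obs_rel <- if (length(observed$intensity) && max(observed$intensity) > 0) {
    observed$intensity / max(observed$intensity) * 100
  } else observed$intensity
  matched_flag <- seq_along(observed$mz) %in% match$pairs$obs
  labels <- if (annotate && !is.null(names(ts))) {
    data.frame(label = names(ts),
               mz = vapply(ts, function(d) {
                 if (nrow(d)) d$mz[which.max(d$intensity)] else NA_real_
               }, numeric(1)))
  } else data.frame(label = character(0), mz = numeric(0))

  open_device(out_path)
  on.exit(grDevices::dev.off())
  xlim <- range(c(flat$mz, observed$mz), finite = TRUE)
  graphics::plot(NA, xlim = xlim, ylim = c(-105, 115), xlab = "m/z",
                 ylab = "relative intensity", yaxt = "n")
  graphics::axis(2, at = seq(-100, 100, 50), labels = abs(seq(-100, 100, 50)))
  graphics::abline(h = 0, col = "gray40")
  graphics::segments(flat$mz, 0, flat$mz, flat$intensity,
                     col = colors$theoretical, lwd = 1.5)
  graphics::segments(observed$mz, 0, observed$mz, -obs_rel,
                     col = ifelse(matched_flag, colors$matched,
                                  colors$unmatched))
  if (nrow(labels)) {
    graphics::text(labels$mz, 108, labels$label, cex = 0.6, srt = 90)
  }
  invisible(list(theoretical = flat,
                 observed = data.frame(mz = observed$mz,
                                       intensity = obs_rel,
                                       matched = matched_flag),
                 labels = labels))
}

#' Plot an isotopic fine structure
#'
#' Peaks closer than the display separation are offset for visual clarity
#' (true positions are kept in the returned data layer), and the most
#' probable isotopologues are annotated with their heavy-isotope
#' compositions.
#'
#' @param fs A `fine_spectrum`.
#' @param top_n_labels Number of species to annotate.
#' @param out_path Image file to write.
#' @param min_separation Display separation in Da (default 0.03).
#' @return Invisibly, the displayed data frame (columns include `mass`,
#'   `true_mass`, `probability`, `label`).
#' @export
fine_structure_plot <- function(fs, top_n_labels = 5L, out_path,
                                min_separation = 0.03) {
  disp <- jitter_overlapping_peaks(fs, min_separation)
  lab_idx <- order(disp$probability, decreasing = TRUE)
  lab_idx <- lab_idx[seq_len(min(top_n_labels, nrow(disp)))]
  disp$label <- ""
  disp$label[lab_idx] <- ifelse(nzchar(disp$composition[lab_idx]),
                                disp$composition[lab_idx], "monoisotopic")
  open_device(out_path)
  on.exit(grDevices::dev.off())
  rel <- disp$probability / max(disp$probability) * 100
  graphics::plot(NA, xlim = range(disp$mass) + c(-0.2, 0.2),
                 ylim = c(0, 115), xlab = "mass (Da)",
                 ylab = "relative abundance")
  graphics::segments(disp$mass, 0, disp$mass, rel, lwd = 1.5)
  has <- nzchar(disp$label)
  graphics::text(disp$mass[has], rel[has] + 6, disp$label[has],
                 col = "red", cex = 0.7, srt = 45, adj = 0)
  invisible(disp)
}

#' Run-summary figures
#'
#' Writes three figures from a [summarize_run()] result: TIC traces per MS
#' level, scan-rate traces, and the precursor-selection map.
#'
#' @param rs A `run_summary`.
#' @param out_dir Output directory.
#' @param format `"png"`, `"pdf"` or `"svg"`.
#' @return Invisibly, the vector of files written.
#' @export
run_plots <- function(rs, out_dir, format = "png") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, paste0(c("tic", "scan_rates",
                                       "precursor_map"), ".", format))
  open_device(paths[1])
  lev <- sort(unique(rs$tic$ms_level))
  graphics::plot(NA, xlim = range(rs$tic$rt), ylim = c(0, max(rs$tic$tic)),
                 xlab = "retention time (min)", ylab = "TIC")
  for (l in lev) {
    d <- rs$tic[rs$tic$ms_level == l, ]
    graphics::lines(d$rt, d$tic, col = if (l == 1) "red" else "blue")
  }
  graphics::legend("topright", legend = paste0("MS", lev),
                   col = c("red", "blue")[seq_along(lev)], lty = 1,
                   bty = "n")
  grDevices::dev.off()

  open_device(paths[2])
  graphics::plot(NA, xlim = range(rs$rates$bin), ylim = c(0, max(rs$rates$scans)),
                 xlab = "retention time (min)", ylab = "scans per bin")
  for (l in lev) {
    d <- rs$rates[rs$rates$ms_level == l, ]
    graphics::lines(d$bin, d$scans, type = "s",
                    col = if (l == 1) "red" else "blue")
  }
  grDevices::dev.off()

  open_device(paths[3])
  graphics::plot(rs$precursors$rt, rs$precursors$precursor_mz, pch = 16,
                 cex = 0.5, xlab = "retention time (min)",
                 ylab = "precursor m/z")
  grDevices::dev.off()
  invisible(paths)
}
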