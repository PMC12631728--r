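#' Read an FT2 file
#'
#' Parses the plain-text centroided-spectrum dialect emitted by the Raxport
#' converter: per scan a header of `S` (scan number, low/high, precursor
#' m/z), `Z` (charge and neutral-ish mass) and `I` metadata lines (key,
#' value; `RetentionTime` in minutes is interpreted, everything else is
#' preserved verbatim in `extra`), followed by peak lines of m/z and
#' intensity with optional resolution/baseline/noise/charge columns. A
#' format note with a worked example ships in `extdata/ft2-format.txt`.
#'
#' @param path File path.
#' @return List of `ms_spectrum`.
#' @export
read_ft2 <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    new_spectrum(cur$mz, cur$int, scan = cur$scan, ms_level = cur$ms_level,
                 rt = cur$rt, precursor_mz = cur$prec, charge = cur$charge,
                 extra = cur$extra)
  }
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln) || startsWith(ln, "H")) next
    parts <- strsplit(ln, "[\t ]+")[[1]]
    if (parts[1] == "S") {
      if (!is.null(cur)) out[[length(out) + 1L]] <- flush(cur)
      if (length(parts) < 2) stop("malformed S line at line ", k)
      scan <- suppressWarnings(as.integer(parts[2]))
      if (is.na(scan)) stop("malformed S line at line ", k)
      prec <- if (length(parts) >= 4) suppressWarnings(as.numeric(parts[4]))
              else NA_real_
      cur <- list(scan = scan, prec = prec, charge = NULL, rt = NA_real_,
                  ms_level = if (is.na(prec)) 1L else 2L,
                  mz = numeric(0), int = numeric(0), extra = list())
    } else if (parts[1] == "Z") {
      if (is.null(cur) || length(parts) < 3) {
        stop("malformed Z line at line ", k)
      }
      cur$charge <- suppressWarnings(as.integer(parts[2]))
      if (is.na(cur$charge)) stop("malformed Z line at line ", k)
      cur$extra$ZMass <- as.numeric(parts[3])
    } else if (parts[1] == "I") {
      if (is.null(cur)) stop("I line before any scan at line ", k)
      key <- parts[2]
      val <- paste(parts[-(1:2)], collapse = " ")
      if (identical(key, "RetentionTime")) {
        cur$rt <- as.numeric(val)
      } else if (identical(key, "MSLevel")) {
        cur$ms_level <- as.integer(val)
      } else {
        cur$extra[[key]] <- val
      }
    } else {
      if (is.null(cur)) stop("peak line before any scan at line ", k)
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) < 2 || any(is.na(vals[1:2]))) {
        stop("malformed peak line at line ", k)
      }
      cur$mz <- c(cur$mz, vals[1])
      cur$int <- c(cur$int, vals[2])
    }
  }
  if (!is.null(cur)) out[[length(out) + 1L]] <- flush(cur)
  out
}

#' Write spectra to an FT2 file
#'
#' @param spectra List of `ms_spectrum` (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ft2 <- function(spectra, path) {
  if (inherits(spectra, "ms_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tExtractor\tisosip", con)
  for (s in spectra) {
    if (!is.na(s$precursor_mz)) {
      writeLines(sprintf("S\t%d\t%d\t%.6f", s$scan, s$scan, s$precursor_mz),
                 con)
    } else {
      writeLines(sprintf("S\t%d\t%d", s$scan, s$scan), con)
    }
    if (!is.na(s$charge)) {
      zm <- s$extra$ZMass
      if (is.null(zm)) {
        zm <- if (!is.na(s$precursor_mz)) {
          mz_to_neutral(s$precursor_mz, s$charge)
        } else 0
      }
      writeLines(sprintf("Z\t%d\t%.6f", s$charge, as.numeric(zm)), con)
    }
    if (!is.na(s$rt)) {
      writeLines(sprintf("I\tRetentionTime\t%.6f", s$rt), con)
    }
    writeLines(sprintf("I\tMSLevel\t%d", s$ms_level), con)
    for (key in setdiff(names(s$extra), "ZMass")) {
      writeLines(paste("I", key, s$extra[[key]], sep = "\t"), con)
    }
    if (length(s$mz)) {
      writeLines(sprintf("%.6f\t%.6f", s$mz, s$intensity), con)
    }
  }
  invisible(path)
}

#' Read an MGF file
#'
#' Standard `BEGIN IONS`/`END IONS` blocks; `PEPMASS`, `CHARGE`,
#' `RTINSECONDS`, `TITLE` and `SCANS` are honored, other headers are kept in
#' `extra`. Retention time is converted to minutes.
#'
#' @param path File path.
#' @return List of `ms_spectrum` (all MS2).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  inblock <- FALSE
  cur <- NULL
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      inblock <- TRUE
      cur <- list(mz = numeric(0), int = numeric(0), scan = NA_integer_,
                  prec = NULL, charge = NULL, rt = NA_real_, extra = list())
    } else if (ln == "END IONS") {
      out[[length(out) + 1L]] <- new_spectrum(
        cur$mz, cur$int, scan = cur$scan, ms_level = 2L, rt = cur$rt,
        precursor_mz = cur$prec, charge = cur$charge, extra = cur$extra)
      inblock <- FALSE
      cur <- NULL
    } else if (inblock && grepl("=", ln, fixed = TRUE)) {
      key <- toupper(sub("=.*", "", ln))
      val <- sub("^[^=]*=", "", ln)
      if (key == "PEPMASS") {
        cur$prec <- as.numeric(strsplit(val, "[ \t]+")[[1]][1])
      } else if (key == "CHARGE") {
        cur$charge <- as.integer(sub("\\+|-", "", val)) *
          (if (grepl("-", val, fixed = TRUE)) -1L else 1L)
      } else if (key == "RTINSECONDS") {
        cur$rt <- as.numeric(val) / 60
      } else if (key == "SCANS") {
        cur$scan <- as.integer(val)
      } else {
        cur$extra[[key]] <- val
      }
    } else if (inblock) {
      vals <- suppressWarnings(as.numeric(strsplit(ln, "[\t ]+")[[1]]))
      if (length(vals) < 2 || any(is.na(vals[1:2]))) {
        stop("malformed peak line at line ", k)
      }
      cur$mz <- c(cur$mz, vals[1])
      cur$int <- c(cur$int, vals[2])
    }
  }
  if (inblock) stop("unterminated BEGIN IONS block")
  out
}

#' Write MS2 spectra to an MGF file
#'
#' @inheritParams write_ft2
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "ms_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    if (s$ms_level != 2L) next
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=scan=%d", s$scan), con)
    if (!is.na(s$scan)) writeLines(sprintf("SCANS=%d", s$scan), con)
    if (!is.na(s$precursor_mz)) {
      writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    }
    if (!is.na(s$charge)) {
      writeLines(sprintf("CHARGE=%d%s", abs(s$charge),
                         if (s$charge < 0) "-" else "+"), con)
    }
    if (!is.na(s$rt)) writeLines(sprintf("RTINSECONDS=%.4f", s$rt * 60), con)
    if (length(s$mz)) writeLines(sprintf("%.6f %.6f", s$mz, s$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read an mzML file
#'
#' Uses the Bioconductor mzR parsing layer and normalizes each scan into the
#' package's `ms_spectrum` container (retention time converted to minutes).
#'
#' @param path File path.
#' @return List of `ms_spectrum`.
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package")
  }
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  pk <- mzR::peaks(h)
  if (is.matrix(pk)) pk <- list(pk)
  lapply(seq_len(nrow(hdr)), function(i) {
    prec <- hdr$precursorMZ[i]
    new_spectrum(pk[[i]][, 1], pk[[i]][, 2],
                 scan = hdr$acquisitionNum[i],
                 ms_level = hdr$msLevel[i],
                 rt = hdr$retentionTime[i] / 60,
                 precursor_mz = if (!is.na(prec) && prec > 0) prec else NULL,
                 charge = if (!is.na(hdr$precursorCharge[i]) &&
                              hdr$precursorCharge[i] > 0) {
                   hdr$precursorCharge[i]
                 } else NULL)
  })
}

#' Read a PSM table (Sipros-style TSV)
#'
#' Extracts per row the scan identifier, peptide sequence (flanking residues
#' like `K.PEPTIDE.R` and bracketed modifications stripped), charge, reported
#' atom % enrichment and search score. The column mapping defaults to the
#' Sipros report layout and is fully configurable; an enrichment column
#' holding labels such as `C13_50.000Pct` is parsed for the number before
#' `Pct`.
#'
#' @param path File path.
#' @param mapping Named list mapping the roles `scan`, `peptide`, `charge`,
#'   `enrichment`, `score` to column names.
#' @param strip_flanks Remove `X.`/`.X` flanking annotations from peptides.
#' @return Data frame with columns `scan`, `peptide`, `charge`,
#'   `enrichment` (atom fraction, `NA` if not reported) and `score`.
#' @export
read_psm_tsv <- function(path,
                         mapping = list(scan = "ScanNumber",
                                        peptide = "IdentifiedPeptide",
                                        charge = "ParentCharge",
                                        enrichment = "SearchName",
                                        score = "Score"),
                         strip_flanks = TRUE) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- unlist(mapping[c("scan", "peptide", "charge")])
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("missing column(s) ", paste(miss, collapse = ", "),
         "; available: ", paste(names(d), collapse = ", "))
  }
  pep <- d[[mapping$peptide]]
  if (strip_flanks) {
    pep <- sub("^[A-Za-z-]\\.", "", pep)
    pep <- sub("\\.[A-Za-z-]$", "", pep)
  }
  pep <- gsub("\\[[^]]*\\]|[^A-Z]", "", pep)
  enr <- rep(NA_real_, nrow(d))
  if (!is.null(mapping$enrichment) && mapping$enrichment %in% names(d)) {
    raw <- d[[mapping$enrichment]]
    enr <- suppressWarnings(as.numeric(raw))
    lab <- regmatches(raw, regexpr("[0-9.]+(?=\\s*Pct)", raw, perl = TRUE))
    has_lab <- grepl("[0-9.]+\\s*Pct", raw)
    enr[has_lab] <- as.numeric(lab)
    enr <- enr / 100
  }
  score <- if (!is.null(mapping$score) && mapping$score %in% names(d)) {
    as.numeric(d[[mapping$score]])
  } else NA_real_
  data.frame(scan = as.integer(d[[mapping$scan]]), peptide = pep,
             charge = as.integer(d[[mapping$charge]]), enrichment = enr,
             score = score, stringsAsFactors = FALSE)
}

#' Summarize an LC-MS/MS run
#'
#' Computes the per-level total-ion-current trace, scan acquisition rates
#' per time bin, and the MS2 precursor map (retention time versus precursor
#' m/z) from a list of scans.
#'
#' @param scans List of `ms_spectrum`.
#' @param time_bin Bin width for scan rates, in minutes (default 1).
#' @return A `run_summary`: list with `tic` (data frame: rt, ms_level,
#'   tic), `rates` (data frame: bin start, ms_level, scans per bin) and
#'   `precursors` (data frame: rt, precursor_mz).
#' @export
summarize_run <- function(scans, time_bin = 1) {
  lev <- vapply(scans, `[[`, integer(1), "ms_level")
  rt <- vapply(scans, `[[`, numeric(1), "rt")
  tic <- vapply(scans, function(s) sum(s$intensity), numeric(1))
  tic_df <- data.frame(rt = rt, ms_level = lev, tic = tic)
  tic_df <- tic_df[order(tic_df$ms_level, tic_df$rt), ]
  rownames(tic_df) <- NULL
  bins <- floor(rt / time_bin) * time_bin
  rates <- as.data.frame(table(bin = bins, ms_level = lev),
                         stringsAsFactors = FALSE)
  rates$bin <- as.numeric(rates$bin)
  rates$ms_level <- as.integer(rates$ms_level)
  names(rates)[3] <- "scans"
  prec <- vapply(scans, `[[`, numeric(1), "precursor_mz")
  keep <- lev == 2L & !is.na(prec)
  structure(list(tic = tic_df,
                 rates = rates[order(rates$ms_level, rates$bin), ],
                 precursors = data.frame(rt = rt[keep],
                                         precursor_mz = prec[keep])),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary> ", nrow(x$tic), " scans (",
      sum(x$tic$ms_level == 1), " MS1 / ", sum(x$tic$ms_level == 2),
      " MS2), ", nrow(x$precursors), " precursors\n", sep = "")
  invisible(x)
}
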