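#' Isotopic fine structure of a formula by Monte Carlo simulation
#'
#' Draws `n_draws` molecules, sampling each element's isotope counts from a
#' multinomial distribution over that element's (possibly enriched)
#' abundances, and tallies identical isotopologue compositions. Low-abundance
#' fine-structure variants appear naturally once `n_draws` is large enough;
#' the exact enumeration in [exact_fine_structure()] is the small-formula
#' oracle.
#'
#' @param f A `chem_formula` (or formula string).
#' @param table An `iso_table`, typically after [apply_enrichment()].
#' @param n_draws Number of simulated molecules (default 1e6).
#' @param seed Integer seed; required so results are reproducible. The
#'   caller's RNG state is left untouched.
#' @param prune_threshold Species with estimated probability below this are
#'   dropped (default 1e-8).
#' @return A `fine_spectrum`: a data frame with columns `mass` (Da),
#'   `probability`, `neutrons` (total extra neutron count) and `composition`
#'   (heavy-isotope string such as `"13C2 18O1"`, empty for the all-light
#'   species), sorted by ascending mass, with the formula, table, draw count
#'   and seed attached as attributes.
#' @examples
#' fs <- simulate_fine_structure(parse_formula("C2"), n_draws = 1e4, seed = 1)
#' @export
simulate_fine_structure <- function(f, table = default_iso_table(),
                                    n_draws = 1e6, seed,
                                    prune_threshold = 1e-8) {
  f <- ensure_formula(f, table)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1) stop("n_draws must be >= 1")
  if (prune_threshold < 0 || prune_threshold >= 1) {
    stop("prune_threshold must be in [0, 1)")
  }

  els <- names(f)
  # heavy-isotope counts per draw, one column block per element
  heavy <- with_seed(seed, {
    blocks <- lapply(els, function(el) {
      d <- table[[el]]
      k <- nrow(d)
      draws <- stats::rmultinom(n_draws, f[[el]], d$abundance)
      if (k == 1) NULL else t(draws[-1, , drop = FALSE])
    })
    do.call(cbind, blocks[!vapply(blocks, is.null, logical(1))])
  })

  if (is.null(heavy) || ncol(heavy) == 0) {
    key <- rep("", n_draws)
  } else {
    key <- do.call(paste, c(split(heavy, col(heavy)), sep = ","))
  }
  tal <- table(key)
  prob <- as.numeric(tal) / n_draws
  counts <- decode_heavy_keys(names(tal), f, table)
  build_fine_spectrum(counts, prob, f, table, prune_threshold,
                      meta = list(n_draws = n_draws, seed = seed,
                                  method = "monte-carlo"))
}

#' Exact isotopic fine structure by complete enumeration
#'
#' Enumerates every isotopologue composition with its exact multinomial
#' probability. Serves as the brute-force oracle for both the Monte Carlo
#' simulator and the FFT envelope; probabilities sum to 1 (within 1e-10)
#' before pruning.
#'
#' @inheritParams simulate_fine_structure
#' @param max_species Guard against combinatorial explosion: error if the
#'   number of compositions would exceed this cap (default 1e6).
#' @return A `fine_spectrum` (see [simulate_fine_structure()]).
#' @examples
#' exact_fine_structure(parse_formula("H2O"))
#' @export
exact_fine_structure <- function(f, table = default_iso_table(),
                                 prune_threshold = 0, max_species = 1e6) {
  f <- ensure_formula(f, table)
  if (prune_threshold < 0 || prune_threshold >= 1) {
    stop("prune_threshold must be in [0, 1)")
  }
  per <- lapply(names(f), function(el) {
    d <- table[[el]]
    cmp <- compositions_of(f[[el]], nrow(d))   # rows: counts per isotope
    lp <- apply(cmp, 1, function(cc) {
      stats::dmultinom(cc, prob = d$abundance, log = TRUE)
    })
    list(counts = cmp, logp = lp)
  })
  n_total <- prod(vapply(per, function(x) nrow(x$counts), numeric(1)))
  if (n_total > max_species) {
    stop("enumeration would produce ", format(n_total, big.mark = ","),
         " species (cap ", format(max_species, big.mark = ","), ")")
  }
  idx <- as.matrix(expand.grid(lapply(per, function(x) seq_len(nrow(x$counts)))))
  logp <- rowSums(vapply(seq_along(per),
                         function(j) per[[j]]$logp[idx[, j]],
                         numeric(nrow(idx))))
  # assemble heavy-isotope counts in element order (skipping light isotope)
  heavy <- do.call(cbind, lapply(seq_along(per), function(j) {
    cc <- per[[j]]$counts[idx[, j], , drop = FALSE]
    if (ncol(cc) == 1) NULL else cc[, -1, drop = FALSE]
  }))
  prob <- exp(logp)
  keep <- prob > 0
  build_fine_spectrum(heavy[keep, , drop = FALSE], prob[keep], f, table,
                      prune_threshold, meta = list(method = "exact"))
}

# all non-negative integer k-part compositions of n (stars and bars)
compositions_of <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- lapply(0:n, function(i) {
    cbind(i, compositions_of(n - i, k - 1), deparse.level = 0)
  })
  do.call(rbind, out)
}

# heavy: matrix of heavy-isotope counts, columns ordered as
# unlist over elements of (isotopes minus the lightest)
build_fine_spectrum <- function(heavy, prob, f, table, prune_threshold, meta) {
  els <- names(f)
  heavy_info <- do.call(rbind, lapply(els, function(el) {
    d <- table[[el]]
    if (nrow(d) == 1) return(NULL)
    data.frame(element = el,
               nucleon = d$nucleon[-1],
               dmass = d$mass[-1] - d$mass[1],
               dneut = d$nucleon[-1] - d$nucleon[1])
  }))
  mono <- monoisotopic_mass(f, table)
  if (is.null(heavy) || is.null(heavy_info) || ncol(heavy) == 0) {
    heavy <- matrix(0, length(prob), 0)
    mass <- rep(mono, length(prob))
    neut <- rep(0L, length(prob))
    compo <- rep("", length(prob))
  } else {
    mass <- mono + as.numeric(heavy %*% heavy_info$dmass)
    neut <- as.integer(heavy %*% heavy_info$dneut)
    lab <- paste0(heavy_info$nucleon, heavy_info$element)
    compo <- apply(heavy, 1, function(h) {
      nz <- h > 0
      if (!any(nz)) "" else paste0(lab[nz], h[nz], collapse = " ")
    })
  }
  keep <- prob >= prune_threshold & prob > 0
  d <- data.frame(mass = mass[keep], probability = prob[keep],
                  neutrons = neut[keep], composition = compo[keep],
                  stringsAsFactors = FALSE)
  d <- d[order(d$mass), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, class = c("fine_spectrum", "data.frame"),
            formula = f, iso_table = table,
            prune_threshold = prune_threshold, meta = meta)
}

# decode "a,b,c" heavy-count keys back into a count matrix
decode_heavy_keys <- function(keys, f, table) {
  ncols <- sum(vapply(names(f), function(el) nrow(table[[el]]) - 1L,
                      integer(1)))
  if (ncols == 0) return(matrix(0, length(keys), 0))
  parts <- strsplit(keys, ",", fixed = TRUE)
  mat <- matrix(as.integer(unlist(parts)), nrow = length(keys),
                ncol = ncols, byrow = TRUE)
  mat
}

ensure_formula <- function(f, table) {
  if (is.character(f)) f <- parse_formula(f, table) else f
}

#' @export
print.fine_spectrum <- function(x, n = 10, ...) {
  f <- attr(x, "formula")
  cat("<fine_spectrum> ", format(f), ": ", nrow(x), " isotopologues, ",
      "total probability ", signif(sum(x$probability), 6), "\n", sep = "")
  print.data.frame(utils::head(x[order(-x$probability), ], n))
  invisible(x)
}

#' Collapse a fine structure into an aggregate envelope
#'
#' Groups isotopologues by total extra-neutron count and sums their
#' probabilities; the result is anchored at the monoisotopic mass. Total
#' probability is conserved exactly.
#'
#' @param fs A `fine_spectrum`.
#' @param spacing Da per extra neutron used when placing aggregate peaks on
#'   the mass axis (default the 13C-12C mass difference, 1.003355 Da, since
#'   CHNOPS envelopes are carbon-dominated; see [envelope_fft()]).
#' @return An `iso_envelope` (see [envelope_fft()]).
#' @export
aggregate_by_nucleon <- function(fs, spacing = 1.003355) {
  stopifnot(inherits(fs, "fine_spectrum"))
  K <- max(fs$neutrons)
  p <- numeric(K + 1)
  agg <- tapply(fs$probability, fs$neutrons, sum)
  p[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  new_envelope(anchor_mass = monoisotopic_mass(attr(fs, "formula"),
                                               attr(fs, "iso_table")),
               spacing = spacing, p = p,
               formula = attr(fs, "formula"))
}

#' Displace overlapping fine-structure peaks for display
#'
#' Isotopologues within one nominal isotope peak can differ by less than the
#' plotting resolution; for display the peaks in each overlapping cluster are
#' spread symmetrically about the cluster centre so all gaps equal
#' `min_separation`, while rank order and probabilities are preserved. The
#' true masses are retained in a `true_mass` column.
#'
#' @param fs A `fine_spectrum`.
#' @param min_separation Minimum displayed gap in Da (default 0.03).
#' @return A `fine_spectrum` with `mass` displaced for display and
#'   `true_mass` holding the original values.
#' @export
jitter_overlapping_peaks <- function(fs, min_separation = 0.03) {
  stopifnot(inherits(fs, "fine_spectrum"))
  out <- fs
  out$true_mass <- fs$mass
  m <- fs$mass
  if (length(m) >= 2) {
    # cluster runs of peaks whose consecutive gaps are below the separation
    gap_small <- diff(m) < min_separation
    cl <- cumsum(c(TRUE, !gap_small))
    for (g in unique(cl)) {
      i <- which(cl == g)
      if (length(i) > 1) {
        centre <- mean(m[i])
        m[i] <- centre + (seq_along(i) - (length(i) + 1) / 2) * min_separation
      }
    }
    out$mass <- m
  }
  out
}

#' Export a fine structure or stick spectrum as a tab-separated table
#'
#' @param x A `fine_spectrum` or a stick-spectrum data frame.
#' @param path Output file path.
#' @param ion Optional list from [ion_spec()]; if given, an `mz` column at
#'   that charge is included.
#' @return `path`, invisibly.
#' @export
write_fine_tsv <- function(x, path, ion = NULL) {
  d <- as.data.frame(x)
  if (!is.null(ion) && "mass" %in% names(d)) {
    d$mz <- mz_from_neutral(d$mass, ion$charge, ion$polarity)
    d$charge <- ion$charge
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ion specification for (de)protonated species
#'
#' @param charge Positive integer charge magnitude.
#' @param polarity `"positive"` (protonation, `[M + zH]z+`) or `"negative"`
#'   (deprotonation, `[M - zH]z-`).
#' @return A list with elements `charge` and `polarity`.
#' @export
ion_spec <- function(charge = 1L, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1) stop("charge must be >= 1")
  list(charge = charge, polarity = polarity)
}
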