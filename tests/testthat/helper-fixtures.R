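# Shared fixtures: the worked peptide used throughout (a microbial peptide
# with one residue of every behaviour class: S-containing C, aromatics,
# basic K/H), and builders for synthetic PSM spectra at a given 13C level.

std_pep <- "HYAHVDCPGHADYVK"

enriched_table <- function(fraction, element = "C", nucleon = 13L) {
  apply_enrichment(iso_table(), element, nucleon, fraction)
}

std_theoretical <- function(fraction, charge = 3L, fragment_charges = 1:2) {
  theoretical_psm(std_pep, enriched_table(fraction), charge = charge,
                  fragment_charges = fragment_charges)
}

std_observed <- function(fraction, seed, nm = noise_model(), charge = 3L) {
  make_observed(std_theoretical(fraction, charge), nm, seed = seed,
                precursor_mz = mz_from_neutral(
                  monoisotopic_mass(peptide_formula(std_pep)), charge),
                charge = charge)
}

# direct-summation convolution, the independent oracle for the FFT route
naive_convolve <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
  }
  out
}

# envelope by repeated naive convolution of single-atom distributions
naive_envelope <- function(f, table = iso_table()) {
  acc <- 1
  for (el in names(f)) {
    d <- table[[el]]
    atom <- numeric(max(d$nucleon) - min(d$nucleon) + 1L)
    atom[d$nucleon - min(d$nucleon) + 1L] <- d$abundance
    for (i in seq_len(f[[el]])) acc <- naive_convolve(acc, atom)
  }
  acc
}

combine_sticks_for_test <- function(ts) {
  do.call(rbind, lapply(ts, function(d) d[c("mz", "intensity")]))
}
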