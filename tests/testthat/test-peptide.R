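test_that("residue and peptide compositions match the standard table", {
  expect_equal(as.integer(residue_formula("G")[c("C", "H", "N", "O")]),
               c(2L, 3L, 1L, 1L))
  expect_equal(as.integer(residue_formula("K")[c("C", "H", "N", "O")]),
               c(6L, 12L, 2L, 1L))
  expect_error(residue_formula("B"), "unknown residue")
  # glycine as a peptide = residue + H2O
  expect_equal(format(peptide_formula("G")), "C2H5NO2")
  ag <- peptide_formula("AG")
  ref <- formula_add(formula_add(residue_formula("A"), residue_formula("G")),
                     parse_formula("H2O"))
  expect_equal(unclass(ag), unclass(ref))
})

test_that("convolution is an identity-preserving, commutative sum rule", {
  x <- c(0.2, 0.5, 0.3)
  expect_equal(convolve_dist(1, x), x)
  c2 <- convolve_dist(c(0.9893, 0.0107), c(0.9893, 0.0107))
  expect_equal(c2, dbinom(0:2, 2, 0.0107), tolerance = 1e-15)
  a <- runif(7); b <- runif(4)
  expect_equal(convolve_dist(a, b), convolve_dist(b, a), tolerance = 1e-15)
  expect_equal(sum(convolve_dist(a, b)), sum(a) * sum(b), tolerance = 1e-12)
  expect_equal(convolve_dist(a, b), naive_convolve(a, b), tolerance = 1e-12)
})

test_that("residue convolution equals the single-shot FFT envelope", {
  for (fr in c(0.0107, 0.5, 0.99)) {
    tab <- enriched_table(fr)
    conv <- precursor_envelope(std_pep, tab, as = "envelope")
    fft <- envelope_fft(peptide_formula(std_pep), tab, trim = 0)
    n <- length(conv$p)
    expect_equal(conv$p, fft$p[seq_len(n)], tolerance = 1e-9)
    expect_lt(sum(fft$p) - sum(conv$p), 1e-9)
  }
  # single residue peptide equals its formula envelope
  g <- precursor_envelope("G", as = "envelope")
  expect_equal(g$p, envelope_fft(peptide_formula("G"), trim = 0)$p[seq_along(g$p)],
               tolerance = 1e-12)
})

test_that("50% enrichment shifts the precursor centroid by n_C/2 neutrons", {
  nat <- precursor_envelope(std_pep, enriched_table(0.0107), as = "envelope")
  fifty <- precursor_envelope(std_pep, enriched_table(0.5), as = "envelope")
  n_c <- peptide_formula(std_pep)[["C"]]
  shift <- envelope_mean(fifty) - envelope_mean(nat)
  expect_equal(shift, n_c * (0.5 - 0.0107), tolerance = 1e-6)
})

test_that("fragment sets satisfy b/y complementarity and counts", {
  fr <- fragment_envelopes("AG", charges = 1L)
  b1 <- fr[[1]]; y1 <- fr[[2]]
  expect_equal(unclass(formula_add(b1$envelope$formula,
                                   y1$envelope$formula)),
               unclass(peptide_formula("AG")))

  n <- nchar(std_pep)
  frs <- fragment_envelopes(std_pep, charges = 1:2)
  expect_length(frs, 2 * (n - 1) * 2)
  expect_error(fragment_envelopes(std_pep, charges = 0), "charge")

  mono_pep <- monoisotopic_mass(peptide_formula(std_pep))
  b <- Filter(function(r) r$series == "b" & r$charge == 1, frs)
  y <- Filter(function(r) r$series == "y" & r$charge == 1, frs)
  for (i in seq_len(n - 1)) {
    bi <- Filter(function(r) r$index == i, b)[[1]]
    yj <- Filter(function(r) r$index == n - i, y)[[1]]
    expect_equal(bi$envelope$anchor_mass + yj$envelope$anchor_mass,
                 mono_pep, tolerance = 1e-9)
  }
})

test_that("incremental b envelopes equal the FFT of each prefix formula", {
  tab <- enriched_table(0.5)
  frs <- fragment_envelopes(std_pep, tab, charges = 1L)
  b <- Filter(function(r) r$series == "b", frs)
  for (i in c(1, 5, 14)) {
    bi <- Filter(function(r) r$index == i, b)[[1]]
    prefix <- substr(std_pep, 1, i)
    ref <- envelope_fft(Reduce(formula_add,
                               lapply(strsplit(prefix, "")[[1]],
                                      residue_formula)),
                        tab, trim = 0)
    expect_equal(bi$envelope$p, ref$p[seq_along(bi$envelope$p)],
                 tolerance = 1e-9)
  }
})

test_that("fragment computation cost is linear in peptide length", {
  convolution_count(reset = TRUE)
  fragment_envelopes(std_pep, charges = 1L)
  n <- nchar(std_pep)
  # b prefixes: n-2 merges; y suffixes: n-2 merges + 1 water fold-in
  expect_lte(convolution_count(), 2 * (n - 1))
  expect_lt(convolution_count(), (n - 1)^2 / 2)
})
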