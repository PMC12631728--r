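test_that("elemental distributions reduce to known closed forms", {
  expect_equal(elemental_distribution("C", 1), c(0.9893, 0.0107),
               tolerance = 1e-12)
  fifty <- enriched_table(0.5)
  expect_equal(elemental_distribution("C", 6, fifty), dbinom(0:6, 6, 0.5),
               tolerance = 1e-12)
  expect_equal(elemental_distribution("C", 0), 1)
  # sulfur has a gap at k = 3: the per-atom distribution keeps the zero
  s1 <- elemental_distribution("S", 1)
  expect_equal(s1[4], 0)
  expect_equal(s1[c(1, 2, 3, 5)], iso_table()$S$abundance, tolerance = 1e-12)
})

test_that("FFT envelope equals the exact enumeration and naive convolution", {
  tab <- iso_table()
  for (fml in c("H2O", "C6H12O6", "C3H5NOS")) {
    f <- parse_formula(fml)
    env <- envelope_fft(f, tab, trim = 0)
    agg <- aggregate_by_nucleon(exact_fine_structure(f, tab))
    n <- max(length(env$p), length(agg$p))
    expect_equal(c(env$p, numeric(n - length(env$p))),
                 c(agg$p, numeric(n - length(agg$p))), tolerance = 1e-9)
    ref <- naive_envelope(f, tab)
    expect_equal(env$p, ref[seq_along(env$p)], tolerance = 1e-10)
  }
})

test_that("degenerate and boundary envelopes behave", {
  full <- apply_enrichment(iso_table(), "C", 13, 1)
  env <- envelope_fft(parse_formula("C"), full)
  expect_equal(env$p, c(0, 1))
  expect_error(envelope_fft(parse_formula(""), iso_table()), "empty")
})

test_that("envelope mean obeys linearity of expectation", {
  for (fr in c(0.0107, 0.2, 0.5, 0.75, 0.99)) {
    tab <- enriched_table(fr)
    f <- parse_formula("C6H12O6")
    env <- envelope_fft(f, tab, trim = 0)
    per_atom <- vapply(names(f), function(el) {
      d <- tab[[el]]
      sum((d$nucleon - d$nucleon[1]) * d$abundance)
    }, numeric(1))
    expect_equal(envelope_mean(env), sum(per_atom * as.numeric(f)),
                 tolerance = 1e-9)
  }
})

test_that("probability is conserved and truncation is reported", {
  env <- envelope_fft(parse_formula("C6H12O6"), trim = 0)
  expect_equal(sum(env$p), 1, tolerance = 1e-9)
  expect_warning(envelope_fft(parse_formula("C100"), enriched_table(0.5),
                              max_k = 10),
                 "drops probability")
})

test_that("stick spectra are charged, spaced and normalized correctly", {
  env <- envelope_fft(parse_formula("C6H12O6"))
  st1 <- envelope_to_sticks(env, ion_spec(1, "positive"))
  expect_equal(max(st1$intensity), 100)
  expect_equal(st1$mz[1], env$anchor_mass + 1.007276466, tolerance = 1e-9)
  st3 <- envelope_to_sticks(env, ion_spec(3, "positive"))
  expect_equal(diff(st3$mz), rep(env$spacing / 3, nrow(st3) - 1),
               tolerance = 1e-9)
  single <- isosip:::new_envelope(100, 1.003355, 1)
  expect_equal(nrow(envelope_to_sticks(single)), 1)
})

test_that("average spacing mode uses the abundance-weighted mass step", {
  envd <- envelope_fft(parse_formula("C6H12O6"), enriched_table(0.5),
                       spacing = "average")
  # carbon dominates: spacing close to, but not exactly, the 13C step
  expect_equal(envd$spacing, 1.003355, tolerance = 1e-3)
  expect_false(isTRUE(all.equal(envd$spacing, 1.003355, tolerance = 1e-9)))
})
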