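test_that("formula parsing reads counts, implicit ones, and accumulates", {
  f <- parse_formula("C6H12O6")
  expect_equal(unclass(f)[c("C", "H", "O")], c(C = 6L, H = 12L, O = 6L),
               ignore_attr = TRUE)
  expect_equal(as.integer(parse_formula("H2O")[c("H", "O")]), c(2L, 1L))
  expect_equal(as.integer(parse_formula("CH3CH2OH")[c("C", "H", "O")]),
               c(2L, 6L, 1L))
  expect_error(parse_formula("C6H12O6Xx2"), "unknown element Xx")
  expect_error(parse_formula(""), "empty")
  expect_error(parse_formula("C0H4"), "zero count")
})

test_that("isotope table is valid and enrichment renormalizes correctly", {
  tab <- iso_table()
  for (el in names(tab)) {
    expect_equal(sum(tab[[el]]$abundance), 1, tolerance = 1e-12)
    expect_false(is.unsorted(tab[[el]]$nucleon, strictly = TRUE))
  }
  # natural 13C stays at 1.07% when "enriched" to its natural value
  nat <- apply_enrichment(tab, "C", 13, 0.0107)
  expect_equal(nat$C$abundance, c(0.9893, 0.0107))
  fifty <- apply_enrichment(tab, "C", 13, 0.5)
  expect_equal(fifty$C$abundance, c(0.5, 0.5))
  full <- apply_enrichment(tab, "C", 13, 1.0)
  expect_equal(full$C$abundance, c(0, 1))
  # three-isotope element: the others keep their natural ratio
  o18 <- apply_enrichment(tab, "O", 18, 0.4)
  expect_equal(o18$O$abundance[3], 0.4)
  expect_equal(o18$O$abundance[1] / o18$O$abundance[2],
               tab$O$abundance[1] / tab$O$abundance[2])
  expect_equal(sum(o18$O$abundance), 1, tolerance = 1e-12)
  expect_error(apply_enrichment(tab, "C", 13, 1.5), "atom_fraction")
  expect_error(apply_enrichment(tab, "C", 14, 0.5), "not a listed isotope")
  # input table untouched
  expect_equal(tab$C$abundance, c(0.9893, 0.0107))
})

test_that("enrichment is idempotent and invertible at the natural fraction", {
  tab <- iso_table()
  once <- apply_enrichment(tab, "S", 34, 0.3)
  twice <- apply_enrichment(once, "S", 34, 0.3)
  expect_equal(once$S, twice$S, tolerance = 1e-12)
  back <- apply_enrichment(once, "S", 34, tab$S$abundance[3])
  expect_equal(back$S$abundance, tab$S$abundance, tolerance = 1e-12)
})

test_that("monoisotopic and expected masses match hand calculations", {
  # NIST monoisotopic masses summed by hand
  expect_equal(monoisotopic_mass(parse_formula("C6H12O6")), 180.063388,
               tolerance = 1e-6)
  expect_equal(monoisotopic_mass(parse_formula("H2O")), 18.010565,
               tolerance = 1e-6)
  expect_error(monoisotopic_mass(isosip:::as_formula(c(Zz = 1L))), "not in table")
  # weighted two-term mean for a single carbon
  expect_equal(expected_mass(parse_formula("C")),
               12 * 0.9893 + 13.00335483778 * 0.0107, tolerance = 1e-9)
  full <- apply_enrichment(iso_table(), "C", 13, 1)
  expect_equal(expected_mass(parse_formula("C"), full), 13.00335483778)
})

test_that("expected mass is affine in the enrichment fraction", {
  f <- parse_formula("C6H12O6")
  fr <- c(0.1, 0.35, 0.6, 0.9)
  em <- vapply(fr, function(x) {
    expected_mass(f, apply_enrichment(iso_table(), "C", 13, x))
  }, numeric(1))
  slopes <- diff(em) / diff(fr)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-9)
  # slope = n_C * (heavy mass - light mass) for two-isotope carbon
  expect_equal(slopes[1], 6 * (13.00335483778 - 12), tolerance = 1e-9)
})

test_that("m/z arithmetic follows (de)protonation and round-trips", {
  expect_equal(mz_from_neutral(180.063388, 1, "negative"), 179.056112,
               tolerance = 1e-6)
  m <- 1234.5678
  expect_equal(mz_to_neutral(mz_from_neutral(m, 1, "positive"), 1), m)
  expect_equal(mz_from_neutral(m, 3, "positive"),
               (m + 3 * 1.007276466) / 3)
  expect_error(mz_from_neutral(0.5, 1, "negative"), "not positive")
  expect_error(mz_from_neutral(100, 0), "positive integer")
})
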