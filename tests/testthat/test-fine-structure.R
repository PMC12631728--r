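test_that("exact enumeration reproduces closed-form species probabilities", {
  c1 <- exact_fine_structure(parse_formula("C"))
  expect_equal(c1$probability, c(0.9893, 0.0107))
  expect_equal(c1$composition, c("", "13C1"))

  # H2O: 3 deuterium splits x 3 oxygen isotopes
  w <- exact_fine_structure(parse_formula("H2O"))
  expect_equal(nrow(w), 9)
  expect_equal(sum(w$probability), 1, tolerance = 1e-10)

  # C6 at 50%: exact binomial coefficients
  fifty <- enriched_table(0.5)
  c6 <- exact_fine_structure(parse_formula("C6"), fifty)
  expect_equal(c6$probability[c6$composition == "13C3"],
               choose(6, 3) / 2^6)
  expect_equal(c6$probability, dbinom(0:6, 6, 0.5), tolerance = 1e-12)
})

test_that("enumeration masses are recomputable from compositions", {
  fs <- exact_fine_structure(parse_formula("C3H5NOS"))
  tab <- iso_table()
  heavy_mass <- function(comp) {
    if (!nzchar(comp)) return(0)
    toks <- strsplit(comp, " ")[[1]]
    sum(vapply(toks, function(t) {
      m <- regmatches(t, regexec("^([0-9]+)([A-Z][a-z]?)([0-9]+)$", t))[[1]]
      d <- tab[[m[3]]]
      (d$mass[d$nucleon == as.integer(m[2])] - d$mass[1]) * as.integer(m[4])
    }, numeric(1)))
  }
  mono <- monoisotopic_mass(attr(fs, "formula"))
  recomputed <- mono + vapply(fs$composition, heavy_mass, numeric(1))
  expect_equal(fs$mass, unname(recomputed), tolerance = 1e-9)
})

test_that("enumeration cap triggers an explicit size error", {
  expect_error(exact_fine_structure(parse_formula("C3H5NOS"),
                                    max_species = 10),
               "species")
})

test_that("Monte Carlo converges to the closed form and to the enumeration", {
  # C2 natural: three species with binomial probabilities; at 1e5 draws the
  # estimate must sit within 4 binomial standard errors of each closed form
  fs <- simulate_fine_structure(parse_formula("C2"), n_draws = 1e5, seed = 11,
                                prune_threshold = 0)
  truth <- c(0.9893^2, 2 * 0.9893 * 0.0107, 0.0107^2)
  se <- sqrt(truth * (1 - truth) / 1e5)
  expect_equal(nrow(fs), 3)
  expect_true(all(abs(fs$probability - truth) < 4 * se + 1e-12))

  # total-variation to the exact enumeration shrinks with draw count
  f <- parse_formula("CH4")
  ex <- exact_fine_structure(f)
  tv_small <- total_variation(
    simulate_fine_structure(f, n_draws = 1e3, seed = 3, prune_threshold = 0), ex)
  tv_big <- total_variation(
    simulate_fine_structure(f, n_draws = 1e5, seed = 3, prune_threshold = 0), ex)
  expect_lt(tv_big, tv_small)
  expect_lt(tv_big, 5e-3)
})

test_that("single-draw simulation yields one species with probability 1", {
  fs <- simulate_fine_structure(parse_formula("C6H12O6"), n_draws = 1,
                                seed = 5)
  expect_equal(nrow(fs), 1)
  expect_equal(fs$probability, 1)
})

test_that("same seed gives bit-identical fine spectra", {
  a <- simulate_fine_structure(parse_formula("C6H12O6"), n_draws = 1e4,
                               seed = 99)
  b <- simulate_fine_structure(parse_formula("C6H12O6"), n_draws = 1e4,
                               seed = 99)
  expect_identical(a$mass, b$mass)
  expect_identical(a$probability, b$probability)
  expect_error(simulate_fine_structure(parse_formula("C"), n_draws = 1e3),
               "seed")
})

test_that("nucleon aggregation conserves probability and regroups correctly", {
  c2 <- exact_fine_structure(parse_formula("C2"))
  env <- aggregate_by_nucleon(c2)
  expect_equal(env$p, dbinom(0:2, 2, 0.0107), tolerance = 1e-12)
  glc <- exact_fine_structure(parse_formula("C6H12O6"), enriched_table(0.5))
  env2 <- aggregate_by_nucleon(glc)
  expect_equal(sum(env2$p), sum(glc$probability), tolerance = 1e-15)
  expect_equal(env2$anchor_mass, monoisotopic_mass(parse_formula("C6H12O6")))
})

test_that("display jitter separates close peaks but preserves order", {
  fs <- exact_fine_structure(parse_formula("C6H12O6"), prune_threshold = 1e-6)
  j <- jitter_overlapping_peaks(fs, 0.03)
  expect_true(all(diff(j$mass) >= 0.03 - 1e-12))
  expect_equal(order(j$mass), order(j$true_mass))
  expect_equal(j$probability, fs$probability)
  # already-separated and single peaks are untouched
  far <- exact_fine_structure(parse_formula("C2"))
  far <- far[far$probability > 1e-4, ]
  class(far) <- class(fs)
  attr(far, "formula") <- attr(fs, "formula")
  attr(far, "iso_table") <- attr(fs, "iso_table")
  expect_equal(jitter_overlapping_peaks(far, 0.03)$mass, far$mass)
})
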