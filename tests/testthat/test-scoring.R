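test_that("denoising keeps locally dominant peaks and is a no-op when sparse", {
  sparse <- new_spectrum(c(100, 200, 300), c(1, 2, 3))
  out <- denoise(sparse, window = 50, top_n = 2)
  expect_equal(out$mz, sparse$mz)
  # one huge peak in a sea of noise, window spanning everything
  s <- new_spectrum(c(seq(100, 199, 1), 150.5), c(rep(1, 100), 1000))
  out <- denoise(s, window = 1000, top_n = 1)
  expect_equal(out$mz, 150.5)
  # injected envelope sticks survive 200 noise peaks at SNR 10
  theo <- theoretical_psm(std_pep, enriched_table(0.0107), charge = 3,
                          include = "precursor")
  obs <- make_observed(theo, noise_model(n_noise_peaks = 200), seed = 21)
  dn <- denoise(obs, window = 100, top_n = 10)
  big <- theo$precursor[theo$precursor$intensity > 15, ]
  hit <- match_peaks(big, dn, tolerance = 0.01)
  expect_gte(nrow(hit$pairs) / nrow(big), 0.9)
})

test_that("greedy matching is exclusive, tolerant and intensity-ranked", {
  theo <- data.frame(mz = c(100, 101, 102), intensity = c(100, 50, 10))
  obs <- new_spectrum(c(100.001, 100.995, 101.005, 150),
                      c(10, 5, 50, 7))
  m <- match_peaks(theo, obs, tolerance = 0.01)
  expect_equal(nrow(m$pairs), 2)
  # the stick at 101 takes the more intense of the two candidates
  expect_equal(m$pairs$obs[m$pairs$theo == 2], 3)
  expect_equal(m$unmatched_theo, 3L)
  expect_true(4 %in% m$unmatched_obs)
  expect_true(!anyDuplicated(m$pairs$obs))
  # identity match has zero error; shifted spectra do not match
  ident <- match_peaks(theo, new_spectrum(theo$mz, theo$intensity), 0.01)
  expect_equal(nrow(ident$pairs), 3)
  expect_equal(ident$pairs$mz_error, rep(0, 3))
  shifted <- match_peaks(theo, new_spectrum(theo$mz + 0.02, theo$intensity),
                         0.01)
  expect_equal(nrow(shifted$pairs), 0)
})

test_that("WDP is maximal for a perfect match and decreases under deletion", {
  # single envelope: a complete proportional match scores exactly 1
  prec <- std_theoretical(0.5)["precursor"]
  po <- new_spectrum(prec$precursor$mz, prec$precursor$intensity)
  expect_equal(score_wdp(prec, po), 1, tolerance = 1e-12)
  expect_equal(score_wdp(prec, new_spectrum(po$mz, po$intensity^2),
                         transform = "sqrt"), 1, tolerance = 1e-12)

  # full set: score approaches one point per envelope (a few fragment
  # sticks collide in m/z, which caps the sum just below the envelope count)
  theo <- std_theoretical(0.5, fragment_charges = 1L)
  perfect <- do.call(rbind, lapply(theo, function(d) d))
  obs <- new_spectrum(perfect$mz, perfect$intensity)
  full <- score_wdp(theo, obs)
  expect_lte(full, length(theo) + 1e-9)
  expect_gt(full, 0.98 * length(theo))
  base_mz <- theo$precursor$mz[which.max(theo$precursor$intensity)]
  keep <- abs(obs$mz - base_mz) > 0.02
  drop1 <- new_spectrum(obs$mz[keep], obs$intensity[keep])
  expect_lt(score_wdp(theo, drop1), full)
  empty <- new_spectrum(numeric(0), numeric(0))
  expect_equal(score_wdp(theo, empty), 0)
  # invariant to uniform intensity scaling
  scaled <- new_spectrum(obs$mz, obs$intensity * 7.3)
  expect_equal(score_wdp(theo, scaled), full, tolerance = 1e-12)
})

test_that("XCorr rewards correlation and cancels flat background", {
  theo <- std_theoretical(0.5, fragment_charges = 1L)
  flat_theo <- combine_sticks_for_test(theo)
  obs <- new_spectrum(flat_theo$mz, flat_theo$intensity)
  expect_gt(score_xcorr(theo, obs), 0)
  # uniform observed: background subtraction cancels the signal
  uni_mz <- seq(200, 1600, by = 1.0005079)
  uni <- new_spectrum(uni_mz, rep(5, length(uni_mz)))
  expect_lt(abs(score_xcorr(theo, uni)), 0.05 * score_xcorr(theo, obs))
  # regional normalization makes the score scale-invariant
  expect_equal(score_xcorr(theo, new_spectrum(obs$mz, obs$intensity * 2)),
               score_xcorr(theo, obs), tolerance = 1e-9)
})

test_that("MVH reproduces direct hypergeometric arithmetic", {
  sticks <- data.frame(mz = c(100, 110, 120, 130), intensity = rep(1, 4))
  obs <- new_spectrum(c(100, 110, 200, 210), rep(5, 4))
  expect_equal(score_mvh(sticks, obs, tolerance = 0.01, n_classes = 1,
                         n_bins = 10),
               -log(90 / 210), tolerance = 1e-9)
  # no theoretical sticks: P = 1, score 0
  none <- data.frame(mz = numeric(0), intensity = numeric(0))
  expect_equal(score_mvh(none, obs), 0)
  # concentrated matches in one class beat scattered matches
  obs6 <- new_spectrum(c(100, 110, 200, 210, 300, 310), c(9, 8, 5, 4, 2, 1))
  conc <- data.frame(mz = c(100, 110), intensity = c(1, 1))
  scat <- data.frame(mz = c(100, 300), intensity = c(1, 1))
  expect_gt(score_mvh(conc, obs6, n_classes = 3, n_bins = 50),
            score_mvh(scat, obs6, n_classes = 3, n_bins = 50))
  # deleting a matched peak never raises the score
  fewer <- new_spectrum(c(100, 200, 210), rep(5, 3))
  expect_lte(score_mvh(sticks, fewer, n_bins = 10),
             score_mvh(sticks, obs, n_bins = 10))
})

test_that("entropy similarity is a bounded symmetric similarity", {
  a <- new_spectrum(c(100, 101, 102), c(10, 50, 20))
  expect_equal(entropy_similarity(a, a), 1, tolerance = 1e-12)
  b <- new_spectrum(200, 5)
  one <- new_spectrum(100, 7)
  expect_equal(entropy_similarity(one, b), 0, tolerance = 1e-12)
  c <- new_spectrum(c(100.002, 101.001, 150), c(12, 40, 15))
  expect_equal(entropy_similarity(a, c), entropy_similarity(c, a),
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:25) {
    x <- new_spectrum(runif(20, 100, 1000), rexp(20))
    y <- new_spectrum(runif(15, 100, 1000), rexp(15))
    s <- entropy_similarity(x, y)
    expect_gte(s, 0); expect_lte(s, 1)
    # invariant to uniform intensity scaling
    y2 <- new_spectrum(y$mz, y$intensity * 100)
    expect_equal(entropy_similarity(x, y2), s, tolerance = 1e-12)
  }
})

test_that("scorers are invariant to observed peak order", {
  theo <- std_theoretical(0.5, fragment_charges = 1L)
  obs <- std_observed(0.5, seed = 33)
  perm <- sample(seq_along(obs$mz))
  obs2 <- new_spectrum(obs$mz[perm], obs$intensity[perm])
  expect_equal(score_wdp(theo, obs2), score_wdp(theo, obs))
  expect_equal(score_mvh(theo, obs2), score_mvh(theo, obs))
  expect_equal(score_xcorr(theo, obs2), score_xcorr(theo, obs))
})
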