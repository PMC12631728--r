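---
title: "Simulating and scoring isotopic enrichment patterns with isosip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring isotopic enrichment patterns with isosip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isosip)
```

## The problem

Stable isotope probing (SIP) feeds organisms isotopically heavy substrates
(^13^C, ^15^N, ^2^H) and reads the incorporation of the label out of mass
spectra. A peptide or metabolite that has assimilated label no longer shows
the familiar natural-abundance isotopic pattern: its isotopic envelope
broadens and shifts by an amount governed by the atom % enrichment of the
labeled element. Interpreting such spectra requires three things this
package provides:

1. **simulation** of isotopic fine structures and aggregate envelopes of
   arbitrary chemical formulas and peptides at any enrichment from 0 to
   100 atom %;
2. **scoring** of peptide-spectrum matches (PSMs) against theoretical
   spectra with several complementary scoring functions; and
3. **estimation** of the enrichment level of a PSM by profiling those
   scores across the whole enrichment grid, with visualization for manual
   validation.

## Models and algorithms

### Isotope bookkeeping

Every simulation starts from a per-element isotope table (nucleon number,
exact mass, abundance; NIST/CODATA values shipped as a plain-text resource
that users can audit or override). An enrichment specification sets the
abundance of one heavy isotope — say ^13^C to 0.50 — and rescales the
remaining isotopes of that element proportionally to their natural ratios.
Proportional renormalization is the standard convention for elements with
three or more isotopes (O, S); for two-isotope elements it reduces to the
obvious complement. Natural ^13^C abundance defaults to 1.07 atom %.

Throughout, the *monoisotopic anchor* of a formula is the all-lightest
composition even when a heavy isotope dominates. Keeping the anchor fixed
means the envelope index k (extra neutrons) has the same meaning at every
enrichment level, which is what makes enrichment profiles comparable.

### Fine structure: multinomial Monte Carlo and exact enumeration

An isotopologue is a specific assignment of isotope counts to every atom.
`simulate_fine_structure()` draws whole molecules: for each element with
count n and abundance vector p, an isotope-count vector is drawn from
Multinomial(n, p); identical compositions are tallied over `n_draws`
(default 10^6) and the tally frequencies estimate isotopologue
probabilities. The species mass is exact, computed from the composition,
so distinct near-isobaric species (e.g. one ^13^C versus one ^15^N) remain
distinct — this is the point of fine structure. A seed is a required
argument; there is no hidden global RNG state, and the same seed gives
bit-identical output.

`exact_fine_structure()` enumerates all compositions with exact
multinomial probabilities (stars-and-bars per element, outer product
across elements). It is the brute-force oracle: before pruning, its
probabilities sum to 1 within 10^-10, and the Monte Carlo total-variation
distance to it shrinks as draws grow (about 10^-3 at 10^6 draws for
glucose). Its enumeration cap (10^6 species by default) errors loudly
rather than silently truncating.

Defaults chosen once and kept: `n_draws` 10^6 and `prune_threshold` 10^-8,
small enough to retain the low-abundance variants that motivate Monte
Carlo simulation while keeping tallies compact.

### Aggregate envelopes by FFT

Ignoring fine structure, the envelope is the distribution of the total
extra-neutron count. Each element's single-atom distribution over k is
Fourier-transformed, raised to the power of its stoichiometric count,
transforms are multiplied pointwise, and one inverse FFT yields the
molecule's envelope — O(K log K) instead of repeated convolution. The grid
is the smallest power of two covering the maximal reachable k, so the
cyclic convolution never wraps; ringing below 10^-12 is clamped to zero,
and explicit truncation warns with the probability mass lost.

Aggregate peaks are placed at `anchor + k × 1.003355 Da` (the ^13^C-^12^C
mass difference) because CHNOPS envelopes are carbon-dominated; a
probability-weighted "average" spacing is available as an option since the
best placement of aggregate peaks is genuinely ambiguous once several
elements contribute neutrons.

### Peptides: residue convolution and b/y fragments

A peptide's envelope is the convolution of its residues' envelopes plus
terminal H and OH. `precursor_envelope()` computes it that way and agrees
with the single-shot FFT of the full formula to ~10^-12 per index. The
payoff of the residue route is incremental fragment computation:
b-ion envelopes are prefixes (b_i from b_(i-1) and one residue) and y-ion
envelopes suffixes, so all 2(n-1) fragment envelopes of an n-residue
peptide cost 2(n-1) convolutions rather than O(n^2); a convolution counter
makes this assertion testable.

Neutral-fragment conventions: b_i is the bare residue sum (the proton is
added at charging), y_j is the residue sum plus water. This makes b/y
complementarity exact — b_i and y_(n-i) neutral formulas add up to the
peptide's, and their monoisotopic masses to the precursor's within
10^-9 Da. Only the b/y series are modeled; fixed modifications can be
supplied as per-residue formula deltas but default off.

### Scoring functions

Four scorers compare a theoretical PSM spectrum (precursor and/or fragment
envelopes) to an observed scan. All are invariant to observed peak order
and to uniform intensity scaling.

* **WDP (weighted dot product).** Per envelope, the cosine between the
  theoretical stick intensities and the matched observed intensities,
  normalized against the self-product of the *full* theoretical envelope:
  a complete proportional match scores exactly 1 per envelope, any missing
  stick strictly lowers it, and the total sums over envelopes so every
  isotopic stick contributes. Observed intensities enter linearly: WDP is
  a shape-matching score, and a square-root variance stabilization (kept
  as `transform = "sqrt"`) measurably flattens envelope shapes and widens
  enrichment profiles — with it, WDP loses its characteristic narrow
  profile peak (35.4% vs 31.3% FWHM for the cross-correlation score on the
  standard 50% fixture; linear intensities give 28.2%). That empirical
  comparison, run during development on noise-free and standard-noise
  fixtures, is why linear is the default.
* **XCorr.** SEQUEST-style cross-correlation: both spectra binned at
  1.0005079 Da, observed intensities square-rooted and normalized to 50 in
  each of ten m/z regions, score = dot product at zero offset minus the
  mean over offsets within ±75 bins, computed with the single-pass
  background-subtraction identity.
* **MVH.** MyriMatch-style multivariate hypergeometric: observed peaks
  ranked into three equal-count intensity classes; the score is -ln of the
  probability of the observed per-class match counts when the theoretical
  sticks sample candidate m/z bins at random. Class boundaries at
  intensity terciles are this package's choice.
* **Spectral entropy.** Peaks aligned within tolerance, each spectrum
  normalized to total 1; similarity = 1 - (2·S_AB - S_A - S_B)/ln 4 with
  S_AB the entropy of the half-half mixture, giving a bounded [0, 1]
  similarity.

Peak matching is greedy in descending theoretical intensity with exclusive
use of observed peaks, tolerance 0.01 Da by default (ppm mode available)
— appropriate for FT-instrument MS2; the scorers' hot path uses an
equivalent vectorized nearest-peak query, exact whenever sticks are
farther apart than twice the tolerance, which holds for isotopic sticks
spaced ~1.003/z Da.

### Enrichment estimation

`score_profile()` regenerates the theoretical spectra at every grid point
(default 0 to 1 in 0.01 steps, i.e. the full 0-100 atom % range) and
scores each against the observed scan; `fit_enrichment()` wraps this into
a fitted-model object. The point estimate is the grid argmax (ties to the
lowest fraction). Peak width is operationalized as the full width at half
maximum of the min-max-normalized profile, linearly interpolated between
grid points — a formalization chosen here because "narrow score peak"
needs a number before it can be compared across scorers; it is invariant
to affine rescaling of scores. Profiles default to scoring precursor plus
fragments; precursor-only and fragments-only modes are exposed because
either can be preferable (e.g. fragments-only when the precursor is
chimeric).

## The synthetic-data generator

`make_observed()` degrades a clean stick spectrum with Gaussian m/z jitter
(σ = 0.002 Da, a well-calibrated FT instrument), lognormal intensity
jitter (CV = 0.2; lognormal keeps intensities positive), and 200 uniform
noise peaks at a signal-to-noise ratio of 10 against the base peak.
`make_run()` simulates a minimal DDA cycle (each MS1 followed by top-N
MS2 scans whose precursors are that MS1's most intense peaks) for
exercising run summaries and file round trips. These emulate the sampling
noise and acquisition structure of real data but not chromatographic peak
shape, co-isolation chimeras, detector saturation, or correlated m/z
drift — so passing recovery tests demonstrates correctness of the
estimator under calibrated noise, not robustness to every pathology of
real runs.

Every stochastic generator takes an explicit seed and reproduces
bit-identically from it.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely from generated
data: 20 formulas (glucose, penicillin, GABA and 17 further CHNOPS
molecules) × 4 enrichment levels for the FFT-versus-enumeration
comparison; 10^6 Monte Carlo draws for glucose; the 15-residue worked
peptide HYAHVDCPGHADYVK (76 carbons) at charge 3 with fragment charges
1-2 for the convolution and scoring checks; 100 seeded replicates per
enrichment level (1.07, 25, 50, 75 atom %) for WDP recovery within one
grid step; and 50 replicates for the profile-width comparison among WDP,
XCorr and MVH.

## Numerical choices and degenerate inputs

* Envelope tails are trimmed below 10^-10 only after the inverse FFT, and
  never the k = 0 anchor; fine-structure pruning happens after
  probabilities are final.
* Enriching the only isotope of a single-isotope element (P) to anything
  below 1 is an error rather than a silent renormalization.
* Empty observed spectra score 0 (WDP, MVH) or yield flat profiles whose
  estimate is reported as `NA`, never a fabricated argmax.
* Ties in the profile argmax resolve to the lowest enrichment; ties in
  peak matching to the smallest m/z error.
* The charge carrier is the proton mass (1.007276466 Da) for both
  polarities; whether a hydrogen-atom mass would be more faithful to some
  instruments is configurable upstream by editing the constants table.

## Known limitations

* Fine-structure m/z accuracy is limited by the shipped isotope masses;
  no electron-mass correction is applied beyond using the proton mass.
* Only protonation/deprotonation adducts, b/y fragment series, and the
  20 canonical residues are modeled; no neutral losses, internal
  fragments, or variable modifications.
* mzML reading delegates to mzR and inherits its format coverage; FT2 is
  pinned to the dialect documented in `extdata/ft2-format.txt`.
* The Monte Carlo tally keys species on full composition; formulas with
  very many heavy-isotope combinations at extreme draw counts are
  memory-bound before they are CPU-bound.

## A worked example

```{r, eval = FALSE}
# glucose fine structure at 50% 13C, negative mode
tab <- apply_enrichment(iso_table(), "C", 13, 0.5)
fs <- exact_fine_structure(parse_formula("C6H12O6"), tab,
                           prune_threshold = 1e-6)
fine_structure_plot(fs, top_n_labels = 5, out_path = "glucose50.png")

# estimate the enrichment of a synthetic PSM
theo <- theoretical_psm("HYAHVDCPGHADYVK", tab, charge = 3)
obs <- make_observed(theo, noise_model(), seed = 1)
fit <- fit_enrichment("HYAHVDCPGHADYVK", obs, charge = 3)
summary(fit)
coef(fit)
```
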