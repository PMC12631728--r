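Package: isosip
Title: Isotopic Envelope Simulation and Enrichment Scoring for Stable
    Isotope Probing Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, scoring and visualization of isotopic patterns of
    peptides and metabolites in stable isotope probing (SIP) proteomics and
    metabolomics. Simulates isotopic fine structures by Monte Carlo sampling
    of per-element multinomial isotope distributions, computes aggregate
    isotopic envelopes of arbitrary formulas by FFT convolution at any atom
    percent enrichment, builds peptide precursor and b/y fragment-ion
    envelopes by sequential convolution of residue envelopes, and scores
    peptide-spectrum matches with weighted dot product, cross-correlation,
    multivariate hypergeometric and spectral-entropy functions. Enrichment
    levels are estimated by profiling scores across the 0-100 atom percent
    grid. Includes readers and writers for MGF, FT2 and mzML spectra,
    Sipros-style PSM tables, synthetic-data generators and
    publication-style plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
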