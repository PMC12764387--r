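Package: cardiowave
Title: Stimulation Regimens and Optical Analysis of Cardiomyocyte Calcium and Contraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying electrically stimulated hiPSC-derived
    cardiomyocyte cultures in silico. Provides a digital twin of a
    programmable stimulation signal generator (biphasic, monophasic and
    alternating monophasic pulse trains; static and linearly ramped
    frequency or pulse-duration schedules; waveform sampling and signal
    fidelity measurement), seeded generators of GCaMP-like calcium movies
    and phase-contrast-like motion movies with full ground truth, and the
    optical analysis pipeline used on such recordings: ROI trace
    extraction with dF/F0 normalization, calcium-transient kinetics
    (full-width at half-maximum, exponential decay constant tau), beating
    synchronicity via the median absolute deviation of peak-arrival
    times, Horn-Schunck optical flow with circular statistics of wave
    directionality, and contraction/relaxation velocimetry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
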