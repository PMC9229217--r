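Package: msprescreen
Title: Two-Stage GC-MS Spectral Library Search with Top-Peak Prescreening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A memory-efficient search engine for gas chromatography-mass
    spectrometry (GC-MS) spectral libraries in NIST MSP text format. Queries
    are scored against library spectra with a weighted sqrt-cosine similarity
    on m/z-scaled intensities. A fast prescreening stage compares the n most
    intense query peaks against a graduated number of library top peaks,
    ranks library spectra by matched-peak count, and passes tiered candidate
    sets (controlled by a threshold R) to the scorer, so that full similarity
    is computed for only a small fraction of the library. Includes an
    evaluation harness that measures the inclusion rate of prescreened
    searches relative to exhaustive searches across top-N cutoffs and
    (n, m, R) parameter grids, a seeded synthetic-spectra generator emulating
    unit-mass and accurate-mass acquisition regimes, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
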