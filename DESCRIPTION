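Package: stoichbench
Title: Benchmarking Site-Level RNA Modification Stoichiometry Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking site-level RNA modification stoichiometry
    calling from direct RNA sequencing. Designs challenge reference sequences
    containing every k-mer with a fixed central target base, simulates
    challenge-style read mixtures with known per-position modification rates,
    reads, writes and validates the bedRMod site-level modification format,
    estimates per-position ground-truth rates from paired modified/unmodified
    read sets, and scores prediction files with a tolerance-aware metric suite
    (RMSE, MAE, median absolute error, deviation range, accuracy and F1 under
    frequency- and position-tolerant matching).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
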