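Package: pegcraft
Title: Design of Enhanced Prime-Editing Guide RNAs and Quantification of
    Editing Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for prime-editing experiments. Designs pegRNAs whose
    reverse-transcription template carries additional same-sense (synonymous)
    mutations at the RTT positions that raise intended editing efficiency
    (spegRNA), and pegRNAs with a C/G-stabilized scaffold small hairpin
    (apegRNA), including their combination and PE3 nicking-sgRNA candidates.
    Scans subject sequences for mismatch-tolerant off-target candidate sites,
    quantifies editing outcomes from amplicon sequencing reads (intended
    edits, unintended indels, incomplete products, scaffold-incorporation
    byproducts, per-position substitution frequencies), simulates amplicon
    reads with known outcome-class proportions, and provides the matching
    statistical reporting (normalization, fold changes, one-tailed Wilcoxon
    signed-rank test, median and interquartile range).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp
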