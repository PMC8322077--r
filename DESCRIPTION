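Package: ggscan
Title: Discovery of N-Terminal Ubiquitination Sites from Diglycine-Remnant Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying N-terminally ubiquitinated proteins from
    diglycine (GG) remnant immunoaffinity-enrichment mass spectrometry. Provides
    in-silico tryptic and semi-tryptic digestion with decoy database construction,
    monoisotopic peptide and fragment mass arithmetic, proteome-aware classification
    of GG-bearing peptide-spectrum matches (N-terminal ubiquitination at the
    initiator methionine or a Met-aminopeptidase neo-N-terminus, genome-encoded
    internal GGX, or canonical K-epsilon-GG), target-decoy false discovery rate
    filtering with linear discriminant rescoring, TMT and label-free quantitative
    filters with Tukey median polish summarization and per-feature linear-model
    contrasts, substrate calling with sequence-preference profiling, and a
    synthetic-data generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
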