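Package: pol2topo
Title: Spike-In Normalized HiChIP Contact Topology and RNA Pol2 Gene Metrics
Version: 0.1.0
Authors@R:
    person("pol2topo", "developers", email = "dev@example.org", role = c("aut", "cre"))
Description: Tools for analysing protein-centric chromatin contact data
    (HiChIP) with exogenous spike-in normalization (AQuA/RRPM). Reads
    HiC-Pro style allValidPairs records, filters short-range ligation
    artefacts, bins contacts, and normalizes them against mouse spike-in
    counts. Thresholded contacts are clustered into 3D features (peaks,
    loops, clusters) by connected-component analysis, annotated against
    transcription-factor peak sets, CpG islands and gene TSS proximity,
    and compared between conditions via log2 fold changes, rank tables
    and aggregate peak analysis (APA). Gene-level RNA polymerase II
    traveling ratios and unloading ratios (PULR) are computed from
    coverage tracks. A synthetic-data module generates miniature genomes
    with planted contact architecture and ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
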