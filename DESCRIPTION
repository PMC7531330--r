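Package: xkmir
Title: Cross-Kingdom MicroRNA Seed Matching, Target Scanning and
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing putative cross-kingdom regulation of human
    transcripts by diet-derived plant microRNAs. Identifies plant mature
    miRNAs whose 5' ends perfectly match human miRNA seed frames (positions
    2-7, 2-8 and 3-8), profiles whole-sequence global-alignment similarity
    against real and random backgrounds, scans transcripts for candidate
    binding sites with a miRanda-style two-phase procedure (weighted
    complementarity alignment followed by nearest-neighbor RNA:RNA duplex
    free-energy evaluation), selects candidate functional analogs from
    validated-target evidence and gene-set over-representation, and performs
    count-based differential expression (median-of-ratios normalization,
    per-gene Fisher's exact test, Benjamini-Hochberg FDR and fold-change
    filtering). Seeded synthetic-data generators with planted ground truth
    make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
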