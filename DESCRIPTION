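Package: poolscreen
Title: Analysis of Pooled In Vivo shRNA Screens from Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification and statistical analysis of pooled short hairpin RNA
    (shRNA) screens read out by amplicon sequencing, as used for in vivo screens
    of germ cell development in mouse testis. Reads are assigned to constructs by
    exact matching of each hairpin's unique half-sequence, technical replicates
    are collapsed by the median, counts are normalized to reads per million and
    expressed as log2 fold changes against the sequenced input pool, and
    per-construct depletion or enrichment is tested with Wilcoxon rank-sum tests
    against the empirical null formed by negative-control hairpins. Genes are
    called essential by the two-hit rule (at least two independently depleted
    constructs), control constructs yield false negative/positive rate estimates,
    and replicate-subsampling and read-thinning utilities reproduce power
    analyses for screen design. A full generative simulator of pooled screens
    (transfection, selection, PCR jackpotting, sequencing) provides ground-truth
    data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
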