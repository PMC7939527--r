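Package: pairedmeth
Title: Paired Tumor/Normal Methylome and Transcriptome Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of paired tumor and matched non-tumor
    tissue profiled on Infinium-style methylation arrays and expression
    arrays. Calls differentially methylated positions from beta values
    with an empirical-Bayes moderated paired t-test on M-values and a
    set of stringent effect-size filters, aggregates them into
    differentially methylated regions by a neighboring-CpG rule, scores
    5-hydroxymethylcytosine from paired bisulfite/oxidative-bisulfite
    beta values and classifies per-CpG methylation-state transitions,
    performs paired differential expression, and merges the layers at
    gene level with Spearman expression-methylation correlation and
    hypergeometric gene-set enrichment. Ships a seeded synthetic-data
    generator with planted ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
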