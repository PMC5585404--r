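Package: convmine
Title: Comparative Transcriptome Mining of Direct Cell Conversions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-analysis toolkit for direct cell-conversion (transdifferentiation)
    expression studies. Computes per-dataset differential expression between origin
    and target cells (fold change plus Welch test on log2 intensities), combines
    direction calls across independent datasets by consensus voting (m-of-n rules
    with optional opposite-call vetoes and fold-change gates), discovers
    conversion-specific signatures with an exception-tolerance rule, intersects
    differentially expressed genes with a transcription-factor target database to
    build directed gene regulatory networks and rank hub regulators by out-degree,
    performs gene-set enrichment with one- and two-sided hypergeometric tests under
    Holm (Bonferroni step-down) correction, and clusters expression profiles by
    hierarchical agglomeration on uncentered correlation. Includes a synthetic
    multi-dataset study generator with planted ground truth for end-to-end
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
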