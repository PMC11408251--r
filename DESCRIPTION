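Package: crossmed
Title: Cross-Species Transcriptome Integration with Candidate-Gene
    Methylation Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrative screening of symptom-associated human blood
    transcriptome changes against fear-memory-retrieval-associated mouse
    hippocampal transcriptome changes. Provides microarray-style
    percentile-shift normalization, per-probe phenotype association
    (Pearson, Spearman, partial correlation, ANCOVA), two-group
    differential expression with Benjamini-Hochberg FDR, cross-species
    symbol matching with direction-consistency classification and
    hybrid-threshold overlap selection, target-gene co-expression
    screening with hypergeometric gene-set overrepresentation, a
    candidate-gene CpG tripartite methylation screen, and mediation
    analysis with bootstrap indirect effects. A synthetic-cohort
    generator with planted effects exercises the full pipeline
    end-to-end and supplies ground truth for calibration tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
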