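Package: panelconcord
Title: Concordance Analysis of Tumor-Only and Tumor-Normal Gene Panel Assays
Version: 0.1.0
Authors@R:
    person("panelconcord", "developers", email = "panelconcord@example.org",
           role = c("aut", "cre"))
Description: Tools to compare the short-variant output of a tumor-only (TO)
    and a paired tumor-normal (TN) next-generation sequencing gene panel on
    the genes the panels share. Provides a validated tab-separated variant
    table dialect (with an optional VCF reader), variant normalization and
    exact-key matching, concordance and discordance rates with group and
    actionability stratification, a five-category attribution of discordant
    calls (germline leakage, reporting caps, caller filtering, low allele
    frequency, unexplained), C>T/G>A artifact spectrum counts, exact
    contingency-table and rank tests, and a synthetic dual-assay cohort
    simulator (germline heterozygotes, cellularity-scaled somatic variants,
    FFPE deamination artifacts, matched-normal read evidence) so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
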