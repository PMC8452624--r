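Package: rigstruct
Title: Structural Genomics of Radiation-Induced High-Grade Glioma Cohorts
Version: 0.1.0
Authors@R: person("RIG", "Structural Genomics Contributors", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for the bespoke structural-genomics
    computations used in cohort studies of pediatric radiation-induced
    high-grade glioma (RIG): classification of copy-number segments as
    gain/loss and focal/broad with arm-level and gene-level alteration
    frequencies; per-chromosome chromothripsis calling from four
    statistical criteria (copy-number oscillation, breakpoint clustering,
    randomness of fragment joins, randomness of fragment order);
    reconstruction of candidate extrachromosomal circular DNA (eccDNA)
    amplicons as cycles over highly amplified segments connected by
    structural-variant adjacencies; germline and somatic mutation-load
    filtering, variants per megabase and substitution spectra with
    between-group comparisons; and the patient-level statistics layer
    (median/range, Fisher exact tests, odds ratios, Kaplan-Meier and
    log-rank).  A seeded synthetic-cohort generator plants every signature
    the downstream stages test for, so the whole pipeline is validated by
    planted-truth recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    VariantAnnotation,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
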