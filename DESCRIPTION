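Package: oncopanel
Title: Purity-Aware CNV Calling, Microsatellite Instability Classification
    and Somatic Variant Prioritization for Targeted Tumor Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a hybrid-capture solid-tumor sequencing
    panel: fractional-coverage normalization against a panel of normals,
    tumor-purity-aware log2-ratio copy-number calling with event credibility
    scoring and copy-neutral LOH flagging, baseline-driven microsatellite
    instability classification, somatic variant deprioritization and
    four-category clinical tier annotation, pharmacogenetic genotyping, and
    the analytical-validation machinery (QC gates, accuracy versus truth
    sets, replicate concordance, VAF coefficient of variation, limit of
    detection, read saturation, cohort alteration frequencies). Seeded
    synthetic-data generators emulate every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
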