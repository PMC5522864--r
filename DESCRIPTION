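Package: zygocall
Title: Transgene Zygosity Genotyping from Log-Phase PCR Peak Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines transgene zygosity (homozygous, hemizygous, null) in
    segregating plant populations from capillary-electrophoresis peak tables
    of log-phase (10-cycle) standard PCR products. Peak height and area are
    normalized against a single-copy reference gene with a population-median
    scale factor, transgenic individuals are split into homozygous and
    hemizygous classes by bimodal valley ("pit") detection on a kernel
    density estimate and by exact one-dimensional two-cluster K-means with
    Sarle's cubic clustering criterion and Tukey-Kramer HSD, and Mendelian
    segregation (3:1, 1:2:1) is tested by Pearson chi-square and
    likelihood-ratio G tests, including confirmation of parental zygosity
    predictions from selfed progeny families. A logistic PCR amplification
    simulator generates peak tables with ground-truth genotypes so the whole
    pipeline can be exercised and validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
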