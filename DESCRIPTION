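Package: canopygwas
Title: UAV Canopy Cover, Plant-Architecture Scoring and Haplotype-Based
    GWAS for a MAGIC Rice Population
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale reimplementation of a field-phenotyping analysis
    for an 8-founder MAGIC rice population: vegetation fraction (VF) from
    top-down RGB plot images via CIELAB a*-channel Otsu segmentation, an
    archery-target (AT) concentric-region score of plant architecture from
    per-plant binary tiles, and a haplotype-based genome-wide association
    scan (per-SNP Kruskal-Wallis over founder groups) with QTL peak calling
    and founder-effect correlation analyses. A synthetic-data module
    (canopy scene renderer, founder-mosaic genotypes, QTL-driven phenotype
    simulator) supplies inputs with known ground truth so every stage is
    testable without field or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
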