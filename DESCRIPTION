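Package: duskit
Title: Molecular-Assisted Distinctness, Uniformity and Stability Testing for
    Inbred Crop Cultivars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A workflow for molecular-assisted DUS (distinctness, uniformity,
    stability) assessment of inbred crop cultivars from SNP and SSR genotype
    panels. Reads diploid biallelic genotypes from VCF, applies minor-allele
    frequency and call-rate (integrity) marker filters, computes allele-sharing
    and shared-allele genetic distances, builds neighbor-joining trees with
    bootstrap support, derives patristic distances, classifies off-type plants
    by a robust distance-outlier rule, estimates per-plant and per-cultivar
    genetic purity from homozygosity, tabulates stable heterozygous loci shared
    between cultivars, and evaluates the robustness of distinctness verdicts
    under random SNP downsampling. Includes a synthetic cultivar-population
    simulator (biparental cross followed by single-seed-descent selfing, with
    pinned heterozygous loci, off-type contamination, missingness and
    genotyping error) that produces ground-truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
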