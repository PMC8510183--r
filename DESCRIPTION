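Package: storagefx
Title: Storage-Condition Effects on Metagenomic Microbiome and Resistome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying the effect of biospecimen storage
    conditions (temperature, duration, freeze-thaw cycles) on inferred
    microbiome composition and antimicrobial resistomes from shotgun
    metagenomic count tables. Implements count-table preprocessing
    (read-pair halving, genome-size normalization, total sum scaling),
    alpha diversity (Chao1, Pielou, Simpson) and rarefaction, Hellinger /
    Bray-Curtis ordination (PCoA, constrained correspondence analysis,
    Procrustes comparison), permutational multivariate statistics
    (PERMANOVA, multivariate dispersion homogeneity, Kruskal-Wallis with
    Dunn post hoc), negative-binomial differential abundance with custom
    size factors, resistance-gene FPKM quantification, spike-in mock
    community background correction, and a synthetic data generator that
    plants known storage effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    cluster,
    withr
Config/testthat/edition: 3
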