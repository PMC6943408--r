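Package: mosscrust
Title: Bryophyte Dominance, Drought Resistance and Moss-Microbiome
    Community Analysis for Karst Rocky Desertification Biocrusts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for screening dominant biocrust
    bryophytes from quadrat surveys (frequency and site-ratio dominance
    indices), scoring drought resistance of candidate mosses by the
    fuzzy membership-function method with grey relational analysis of
    the physiological indexes, and characterizing the mosses' symbiotic
    bacterial and fungal communities: alpha diversity (Chao1, Shannon,
    Good's coverage, Faith's PD), Bray-Curtis and unweighted UniFrac
    beta diversity with NMDS and UPGMA clustering, Venn core/exclusive
    OTUs, PERMANOVA, LEfSe-style biomarker discovery, DCA-selected
    constrained ordination, ecological guild annotation from rule
    tables, and thresholded Spearman co-occurrence networks with
    topology metrics. Includes a seeded synthetic-data generator that
    reproduces the statistical structure of the 18-sample two-moss,
    three-habitat study design so every stage runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vegan,
    ape,
    phangorn,
    picante,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
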