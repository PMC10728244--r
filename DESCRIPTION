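Package: sharedzotu
Title: Shared and Host-Specific Faecal Microbiome ZOTUs Across Syntopic Host Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for occurrence-based analysis of replicated amplicon (16S rRNA)
    ZOTU count tables from faecal samples of multiple co-occurring host species.
    Implements a control/replicate/tag-jump/taxonomy/rarity quality-control cascade
    with a per-stage audit report; incidence-based richness extrapolation (Chao2 and
    first-order jackknife with standard errors), sample-based accumulation curves,
    and mean ZOTU incidence with bias-corrected and accelerated (BCa) bootstrap
    confidence intervals; fixed-fixed (quasi-swap and curveball) null models of ZOTU
    sharedness across host species summarised with highest density continuous
    intervals; presence/absence community comparison (binary Bray-Curtis/Sorensen
    dissimilarity, PERMANOVA, multivariate dispersion homogeneity), core-ZOTU
    ranking and class-level composition; and a calibrated synthetic-data generator
    for end-to-end testing without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    boot,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
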