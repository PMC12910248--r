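Package: glymphomics
Title: Glymphatic MRI Markers, Multi-Omics Group Statistics, and Serial
    Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying brain glymphatic (perivascular waste
    clearance) function alongside gut-microbiome and plasma-metabolome
    data. Computes five MRI-derived glymphatic markers from derived
    volumes and time series: the DTI-ALPS diffusivity ratio, a
    single-shell two-compartment free-water fit, Frangi-vesselness
    perivascular-space segmentation, the choroid-plexus volume fraction,
    and BOLD-CSF cross-correlation coupling. Provides group-level
    statistics for omics and marker tables (Bray-Curtis ordination,
    seeded PERMANOVA, covariate-adjusted Kruskal-Wallis with Dunn post
    hoc, summary-statistic ANOVA, chi-square, and an auditable
    metabolite quality-control chain), partial Spearman correlation,
    and a serial two-mediator bootstrap mediation model with the full
    pathway decomposition. A synthetic-data module generates every
    input with known ground truth so the whole pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
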