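Package: coldmap
Title: Association Mapping and Breeding Screens for Cold Tolerance on
    Multi-Allelic SSR Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for marker-trait association analysis of structured inbred
    germplasm genotyped with multi-allelic SSR (microsatellite) markers, as used
    in rice cold-tolerance studies. Provides per-marker fixed-effect GLM scans
    within subpopulations, a sequential significance-level adjustment of the form
    alpha*(1-alpha)^R, the relative genotypic effect (RGE) statistic with z-based
    classification of favourable and unfavourable alleles, frequency-weighted
    multi-allelic linkage-disequilibrium r2 with distance binning, the Evanno
    delta-K helper for STRUCTURE LnP(D) output, and marker-assisted-selection
    pyramiding screens. Includes a two-subpopulation genotype/phenotype simulator
    with planted QTL effects for power and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
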