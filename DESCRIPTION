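Package: glycorr
Title: Cross-Platform Correlation of Glycomics, Metabolomics, and Worm-Size Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fusing targeted LC-MS/MS glycomics, NMR metabolomics,
    and large-particle flow cytometry (Biosorter) population data collected on
    the same biological samples. Computes permethylated glycan monoisotopic
    masses and lithiated m/z values from residue compositions, performs
    targeted MS2 quantification with background filtering and two-fold
    total-ion-current normalization, bins Biosorter time-of-flight/extinction
    event clouds into mass-normalized population maps, integrates declarative
    NMR regions of interest after probabilistic quotient normalization, and
    links the three platforms through STOCSY/SHY driver-peak Pearson
    correlations, thresholded correlation networks, and developmental-profile
    clustergrams. A seeded synthetic-data generator with known ground truth
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
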