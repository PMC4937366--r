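Package: paleoproof
Title: Multi-Proxy Authentication and Identification of Ancient Skeletal Remains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for re-evaluating purportedly ancient human skeletal
    material with independent molecular proxies: authentication of ancient
    mitochondrial DNA by terminal cytosine-deamination profiling with a
    conditional opposite-end filter, hominin lineage assignment from
    branch-diagnostic mtDNA positions, collagen preservation quality control
    (yield and atomic C:N), single-date radiocarbon calibration with highest
    posterior density intervals, and taxonomic identification from collagen
    peptide mass fingerprints (ZooMS). A fully parameterised synthetic-data
    generator produces genome panels with planted diagnostic sites, damaged
    and contaminated read sets, collagen records and MALDI-TOF peak lists
    with known ground truth, so every stage of the pipeline can be exercised
    and calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
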