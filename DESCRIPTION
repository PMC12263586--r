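Package: enhancerquant
Title: Quantitative Dissection of Enhancer Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative side of cis-regulatory enhancer
    dissection experiments: simulation of fluorescence reporter limb images
    with known ground truth, Otsu-based quantification of reporter (GFP)
    activity normalized to transfection control (RFP) within anatomical
    masks, protein binding microarray (PBM) 8-mer relative-affinity scanning
    of candidate transcription-factor binding sites, construct and motif
    bookkeeping for enhancer fragments and site-directed mutants, and the
    nonparametric group-comparison statistics (Kruskal-Wallis with Dunn's
    post hoc, Mann-Whitney U) used to report such assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    stats,
    tools,
    utils,
    EBImage,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
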