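Package: selfiedpcr
Title: Absolute Transcript Quantification with Selfie Digital PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for Selfie droplet digital PCR (dPCR)
    experiments, which measure the absolute number of RNA transcripts per
    copy of the encoding gene by quantifying the same amplicon in paired
    aliquots with (RT+) and without (RT-) reverse transcriptase. Provides
    readers for droplet amplitude tables and plate layouts, reproducible
    fluorescence thresholding, Poisson occupancy estimation with exact and
    delta-method confidence intervals, volumetric back-calculation through
    the dilution chain, the transcripts-per-gene statistic and its derived
    metrics (copies per genome, transcripts per genome, strand-specific
    mitochondrial transcription, RNA-interference silencing), replicate
    statistics, and a generative simulator of droplet experiments for
    validation without instrument data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
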