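Package: dropscreen
Title: Quantitative Analysis of Droplet-Microfluidics Functional Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for water-in-oil droplet (WODL) screening of
    microbial enzyme activity: image-based estimation of cell occupancy inside
    droplets and its calibration to OD600, Baranyi-Roberts growth-curve
    fitting, Poisson single-cell encapsulation statistics,
    fluorescence-activated droplet sorting (FADS) gate arithmetic, OTU
    enrichment scoring across a sort, and protease activity normalisation
    against fluorogenic and Bradford standard curves. Includes synthetic-data
    generators with known ground truth for every pipeline input, so the whole
    workflow is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr
Suggests:
    deSolve,
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
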