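Package: receptorQuant
Title: Quantitative Fluorescence Microscopy and Pharmacology of Membrane
    Receptor Signaling
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for quantifying G-protein-coupled receptor
    oligomerization, mobility, trafficking and pharmacology from
    fluorescence data. Implements molecular-brightness (moment and
    SpIDA-style histogram) oligomerization fingerprinting of
    photon-counting confocal images, line-scan spatiotemporal image
    correlation spectroscopy (STICS) and two-color cross-correlation for
    membrane diffusion and co-diffusion, three-parameter Hill
    concentration-response fitting with the normalization schemes of
    FRET, BRET, NanoBiT and reporter assays, endosome counting and
    membrane-recruitment kinetics from image time series, and one-site
    total-plus-nonspecific saturation radioligand binding analysis with
    isotope decay correction. A synthetic-data module simulates
    photon-counting images of membrane-diffusing emitters, two-color
    line-scan kymographs, dose-response tables, endosome image frames,
    recruitment traces and binding tables with embedded ground truth, so
    every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    minpack.lm,
    tiff,
    yaml,
    mgcv,
    pracma,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, Pharmacodynamics, Spectroscopy,
    SingleCell, Visualization
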