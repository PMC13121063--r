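Package: pbmap
Title: Autofluorescence Photobleaching Kinetics Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for mapping autofluorescence photobleaching kinetics in
    time-lapse skin imaging. Fits a single-exponential decay model
    I(t) = A*exp(-t/tau) + C to every pixel of a stabilized frame stack,
    assembles amplitude, decay-constant and residual-component parameter maps,
    designates lesion core and junction regions via SLIC superpixels,
    compares regions with nonparametric statistics (Levene, Kruskal-Wallis,
    Dunn-Bonferroni), and quantifies the mismatch between intensity-defined
    and kinetics-defined lesion boundaries. Includes a synthetic phantom
    generator with known ground-truth kinetics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    minpack.lm,
    car,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
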