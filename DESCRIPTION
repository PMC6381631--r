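Package: isoresolve
Title: Resolution-Dependent Natural Abundance and Tracer Impurity
    Correction for Stable Isotope Labeling LC-MS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts measured isotopolog fractional abundances (FAM) from
    high-resolution LC-MS stable isotope labeling experiments into mass
    distribution vectors (MDV) and isotopic enrichments, correcting for
    natural isotope abundance and tracer isotopic impurity in a
    resolution-dependent manner.  Two resolution-aware constructions of the
    correction matrix are provided: mass difference theory (MDT), which
    prunes unresolvable isotope combinations using the analyzer's
    mass-dependent resolving power, and an unlabeled-sample-based method
    (ULS) that builds the matrix semi-empirically by repeated deconvolution
    of the tracer element's single-atom abundance vector.  A
    resolution-naive baseline (NRE) and an exhaustive isotope
    fine-structure simulator (used for validation data generation) are
    included, together with non-negative least-squares inversion of the
    correction model and CSV/TSV table input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
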