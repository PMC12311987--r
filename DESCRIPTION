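Package: shapemed
Title: Genome-Wide Causal Mediation Analysis with Elastic Shape Mediators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how genetic variants influence a scalar
    clinical outcome through the shape of an anatomical structure traced as
    a planar landmark contour. Contours are represented as square-root
    velocity functions (SRVF), aligned over rotation and reparameterization
    against a Karcher-mean atlas, and used as functional mediators in a
    two-model causal mediation framework: a shape-on-scalar regression of
    the aligned SRVF on the variant and clinical confounders, and a
    scalar-on-shape regression of the outcome on the variant, the mediator
    functions, and confounders. The package estimates average direct,
    indirect, and total effects, the spatial indirect-effect curve along
    the contour, and the mediation proportion, with wild-bootstrap
    confidence intervals and simultaneous confidence bands. A fast per-SNP
    screening step with false-discovery-rate control selects candidate
    variants, and a synthetic-data generator reproduces the full
    genotype-shape-outcome generative structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
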