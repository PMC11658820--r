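Package: sorghumnet
Title: Grain Counting in Sorghum Panicle Images by Density-Map Regression
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the number of grains in smartphone images of sorghum
    panicles. Point annotations of visible grains are turned into Gaussian
    density maps whose integral equals the grain count; a multicolumn
    convolutional network (Sorghum-Net) is trained to regress those maps
    from masked panicle patches, and a polynomial calibration model maps the
    one-side visible count to the whole-panicle grain number. Includes a
    synthetic panicle-scene generator with exactly known annotations so the
    full pipeline can be trained and validated without field data, LabelMe
    point-annotation I/O, an annotation-consistent augmentation engine, and
    a command-line interface for the end-to-end workflow.
License: MIT
Encoding: UTF-8
Imports: jsonlite, png, yaml, stats, utils, graphics, grDevices, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, EBImage
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
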