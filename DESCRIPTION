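Package: torsdiff
Title: Internal-Coordinate Diffusion for Target-Conditioned Peptide Backbone Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A denoising-diffusion framework that generates peptide-binder
    backbones in internal coordinates (backbone dihedrals and bond angles),
    conditioned on a target protein through a resolution-weighted,
    multimodal context consumed by a cross-attention transformer decoder.
    Amino-acid sequences are co-generated by a parallel decoder branch,
    Cartesian backbones are reconstructed with the Natural Extension
    Reference Frame (NeRF) algorithm, and designs are scored with an
    interface/topology/physicochemistry metric suite. Includes a synthetic
    fixture generator for fully self-contained training and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
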