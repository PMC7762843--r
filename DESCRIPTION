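Package: sourcemvpa
Title: Region-Based MVPA, RSA and Temporal Generalization for Source-Space MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate pattern analysis of source-reconstructed MEG epochs
    organised by cortical region. Implements pairwise linear-discriminant
    decoding on per-region principal-component features with pseudo-trial
    averaging, representational similarity analysis against a binary
    recognition model RDM with a nine-component RDM-profile decomposition,
    a power-versus-pattern dissociation based on RMS power of the feature
    scores and the angle between discriminant normals, temporal
    cross-category generalization matrices with cluster-based sign-flip
    permutation inference, and a synthetic source-data generator emulating
    a pre/post perceptual-training design with injectable power-gain,
    pattern-rotation and delayed-shared-pattern effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
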