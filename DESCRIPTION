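Package: sketchtw
Title: Randomized Sketching Diagnostics via the Tracy-Widom Law
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Data-oblivious randomized sketches (Gaussian, subsampled
    randomized Hadamard, Clarkson-Woodruff/CountSketch, uniform row
    subsampling) for tall design matrices, together with Tracy-Widom
    approximations to the probability that a sketch is an
    epsilon-subspace embedding and to the convergence probability of
    sketch-preconditioned iterative least squares. Includes Monte-Carlo
    oracles based on the Wishart representation of the sketched Gram
    matrix, a preconditioned least-squares fitter with standard S3
    methods, leverage-score diagnostics, synthetic data generators with
    autoregressive column dependence, and experiment drivers that
    compare empirical and theoretical embedding and convergence
    probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
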