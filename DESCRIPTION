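Package: cdtmorph
Title: Ensemble Average Propagator Templates and Cauchy Deformation
    Tensor Morphometry for Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for group analysis of high angular resolution
    diffusion imaging (HARDI). Voxel-wise ensemble average propagators
    (EAPs) are represented as Gaussian mixture fields over a shared
    diffusion dictionary and estimated from diffusion-weighted volumes
    by nonnegative ridge least squares. An unbiased "sharp" population
    template is built in two stages: groupwise diffeomorphic
    registration of the mixture fields under a closed-form L2 mixture
    distance with preservation-of-principal-direction reorientation,
    followed by projection of the intermediate average onto the orbit
    of a population member. Morphometry uses the Cauchy deformation
    tensor sqrt(J J') of each subject-to-template warp, analysed on the
    manifold of symmetric positive-definite matrices via Frechet means,
    principal geodesic analysis, and a permutation-calibrated tangent
    space Hotelling test, with nu-SVM classification of the reduced
    features. A synthetic HARDI phantom generator provides ground-truth
    fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    e1071
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    pracma
Config/testthat/edition: 3
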