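Package: paniclebayes
Title: Unsupervised Bayesian Segmentation of Rice Panicles in Canopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pixel-level segmentation of rice panicles in RGB canopy
    images by unsupervised Bayesian learning. Pixel intensities are
    modeled with a multivariate Gaussian mixture whose weights, means,
    and precision matrices are learned per image by Gibbs sampling
    under conjugate Dirichlet and Normal priors and a non-informative
    Wishart prior. Post-burn-in posterior label probabilities drive a
    maximum a posteriori classifier and a threshold rule for the
    panicle class, identified as the component with the largest total
    channel mean. Includes k-means++ initialization (doubling as a
    baseline segmenter), merging of illumination-split clusters,
    anomaly-cluster detection, pixel-level evaluation with ROC sweeps,
    a synthetic canopy-scene generator with known ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    png,
    stats,
    tools,
    utils
Suggests:
    EBImage,
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
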