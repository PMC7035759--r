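# paniclebayes

Unsupervised Bayesian segmentation of rice panicles in RGB canopy
images, for plant phenotyping work where labeled training data is
scarce and imaging conditions (illumination, altitude, growth stage)
vary from image to image.

Instead of training a classifier, the method learns the statistical
structure of each image on its own. Pixel intensities
`x_i ∈ [0,1]^3` are modeled as a k-component multivariate Gaussian
mixture,

    x_i | z_i = j  ~  N_p(μ_j, Φ_j⁻¹),     Pr(z_i = j) = q_j,

with conjugate priors `q ~ Dirichlet(α)`, `μ_j ~ N_p(τ_j, Ω_j⁻¹)` and
the non-informative prior `π(Φ_j) ∝ |Φ_j|^((p+1)/2)` on the precision
matrices. All parameters are learned per image by Gibbs sampling
(`T = 150` sweeps, burn-in `T0 = 75` by default), and the per-pixel
posterior membership probabilities are the indicator averages over
the retained sweeps. Components are kept identifiable across sweeps
by relabeling them in decreasing order of the total channel mean
`m_j = Σ_c μ_{j,c}`; the panicle class is the component with the
largest `m_j`. A pixel is declared panicle when its posterior
probability of that component reaches the threshold `p_TH = 0.9990`.
For images with uneven illumination or bright foreign objects, runs
with `k > 3` are post-processed: clusters whose means are closer than
`ε_m = 0.1` are merged, and clusters with `m_j ≥ ε_a = 0.9` are
flagged as anomalies and excluded before panicle identification.

The package implements the full pipeline (k-means++ initialization,
the four conjugate full-conditional samplers, posterior averaging,
MAP and thresholded classification, merging and anomaly detection),
pixel-level evaluation with ROC sweeps, a synthetic canopy-scene
generator with exact ground truth, PNG/JPEG image I/O, and a command
line. See `vignettes/unsupervised-panicle-segmentation.Rmd` for the
model, conventions, and limitations.

## Worked example

```r
library(paniclebayes)

# a 120 x 120 synthetic canopy scene with known ground truth
sc  <- generate_scene(scene_spec(height = 120, width = 120, seed = 2024))
seg <- panicle_segment(sc$pixels, run_config(seed = 7))
seg
#> panicle_segmentation: 120 x 120 image, 3 components -> 3 merged clusters
#> total channel means: 0.8306, 0.5811, 0.1698
#> panicle component: 1  | mask covers 6.167 % of pixels at threshold 0.999

truth <- sc$labels == which(sc$class_names == "panicle")
m <- seg_metrics(confusion(seg$panicle_mask, truth))
sprintf("recall %.4f  precision %.4f  F1 %.4f", m$recall, m$precision, m$f1)
#> "recall 1.0000  precision 1.0000  F1 1.0000"
```

The three total channel means are the posterior component brightness
sums — panicle (0.83), leaf (0.58), background (0.17) — and the mask
covers 6.2% of the scene, matching the generator's 6% panicle
prevalence. On this noise level the classes are well separated, so
the thresholded mask reproduces the ground truth exactly.

The same pipeline from a shell:

```sh
Rscript inst/cli/paniclebayes simulate --output sim --height 120 --width 120 --seed 2024
Rscript inst/cli/paniclebayes segment --input sim/scene.png --output out \
        --truth sim/truth_mask.png --posterior-map
cat out/metrics.tsv
```

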