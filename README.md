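# roughseg

EM image segmentation with a **rough-set bounded, spatially constrained,
asymmetric Gaussian mixture model**, for 2-D grayscale or multichannel
images (synthetic phantoms, brain MR slices, color images in Lab space).
It is aimed at users who need mixture-model segmentation that stays robust
under heavy noise without smearing edges — e.g. tissue labeling of noisy MR
slices — and at methodologists who want a tested, reproducible reference
implementation of bounded-support mixtures with Monte-Carlo normalization.

## The model

The image $X=\{x_i\}$ is modeled as
$p(x_i) = \sum_{k=1}^K \pi_{ik} \sum_{l=1}^L \eta_{ikl}\,
\tilde\Psi(x_i\mid\mu_{kl},\Sigma_{kl})$, where each cluster is an
*asymmetric* mixture of $L$ Gaussians that are *bounded*: truncated by a
graded indicator $\tilde H(x\mid\Omega_k)\in[0,1]$ and renormalized by a
Monte-Carlo estimate of $\int \Phi\,\tilde H\,dx$. The indicator comes from
rough-set theory: two adaptive thresholds $t_1 \le t_2$ on the 3×3
neighborhood distance $d_i(\mu_k)=\sum_{m\in\partial_i}\|x_m-\mu_k\|^2 /
(9\,(J_{max}-J_{min}))$ split every cluster's pixels into positive
($\tilde H = 1$), boundary (linear ramp) and negative ($\tilde H = 0$)
regions, and the E-step posteriors are hard-overridden to 1/soft/0 by
region. Two directional spatial priors $E_{ik}$, $F_{ikl}$ — softmaxed
averages of posterior + prior over the best-aligned 3-pixel direction —
smooth the segmentation while preserving edges. Parameters are estimated by
EM with Monte-Carlo bias corrections in the mean and covariance updates;
quality is scored by CCR (correct classification ratio after maximum-overlap
label matching), the Dice coefficient, and the probabilistic Rand index.
The methods vignette (`vignettes/rough-set-bounded-mixtures.Rmd`) derives
the pieces and documents every numerical choice.

## Worked example

```r
library(roughseg)

ph  <- make_phantom(size = 128, luminances = c(0, 1/3, 2/3, 1))
img <- add_gaussian_noise(ph$image, mean = 0, variance = 0.07,
                          seed = 1, clip = TRUE)
fit <- fit_rsbgmm(img, K = 4, L = 3, mc_samples = 10000, seed = 1)
fit
#> rough-set bounded asymmetric GMM segmentation
#>   128 x 128 pixels, K = 4 clusters, L = 3 components
#>   100 iteration(s), not converged (final objective 86013.2138)
ccr(fit$labels, ph$labels)
#> [1] 0.8105469
```

The phantom has four luminance classes corrupted by Gaussian noise whose
standard deviation (0.26) is most of the class spacing (0.33) — per-pixel
classification alone would be ~61% accurate here, so the 0.81 CCR is almost
entirely the work of the neighborhood machinery (the vignette quantifies
each mechanism's share). `tidy(fit)` returns the per-component means,
variances, weights and truncation constants; `glance(fit)` a one-row
summary; `plot(fit)` the label map. `write_result(fit, "out/")` writes the
label-map PNG, per-cluster posterior PNGs and a JSON run record, and
`write_region_maps()` renders each cluster's positive/boundary/negative
regions. Command-line wrappers (`segment.R`, `simulate.R`, `evaluate.R`)
live in `inst/cli/`.

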