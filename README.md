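# perfusionBSN

Self-supervised denoising and quantification of dynamic contrast-enhanced
(DCE) pulmonary perfusion MRI.

Pulmonary perfusion MRI suffers from low SNR (low lung proton density,
short T2*, fast undersampled acquisition), and clean training images
cannot be acquired — so supervised denoisers are off the table, and the
noise is spatially correlated and spatially varying, which breaks the
assumptions of pixel-independent self-supervised methods. This package is
for researchers working on perfusion image quality and quantification who
need a fully reproducible, ground-truth-testable implementation of the
blind-spot + plug-and-play approach to this problem.

## What it implements

**PnP-BSN** — an asymmetric pixel-shuffle-downsampling blind-spot network
(AP-BSN) inside a plug-and-play ADMM iteration:

- a blind-spot CNN (two branches with centrally masked 3×3 / 5×5
  convolutions and dilated residual blocks, s = 2 and 3) whose receptive
  field structurally excludes the center pixel — trained with an L1
  self-supervised loss on single noisy slices, pixel-shuffle-downsampled
  with stride 5 to break noise correlation;
- inference at the smaller stride 2 with T = 16 random-replacement
  refinement passes, averaged;
- the PnP coupling of the trained denoiser D to the noisy image y:

      argmin_{x,z} ½‖y − x‖² + (ρ/2)‖x − z‖²   s.t.  z = D(x + u)

  solved by scaled ADMM (x ← (y + ρ(z − u))/(1 + ρ); z ← D(x + u);
  u ← u + x − z) with ρ = 1 and K = 3 iterations.

**Quantification** — background subtraction, peak-phase selection,
maximum intensity projection, pixel-wise fractal-dimension maps
(differential box counting on the intensity surface; FD = 2 flat baseline,
→ 3 for maximal roughness), 3-class k-means intensity segmentation, and
objective metrics (PSNR, SSIM, region SNR, gradient sharpness), plus a
tuned Gaussian-filter baseline.

**Synthetic phantom** — a seeded lung-perfusion phantom (two lungs,
recursive bifurcating vascular trees, bolus-like enhancement, optional
perfusion-deficit lesion) with spatially correlated, gain-modulated
Gaussian noise and full ground truth; all tests run against it. The
network, backpropagation and optimizer are implemented in base R with
BLAS-backed convolutions; no deep-learning framework is required.

## Worked example

```r
library(perfusionBSN)

# phantom with ground truth
bundle <- simulatePhantom(phantomSpec(), noiseSpec(baseSigma = 20, seed = 1),
                          seed = 1)
sub  <- backgroundSubtract(noisySeries(bundle), "auto")
peak <- selectPeakFrame(sub, lungMask(bundle))
y    <- seriesData(sub)[peak, 6, , ]          # one noisy peak-phase slice

# self-supervised training on noisy slices only (small demo run)
slices <- lapply(2:11, function(s) seriesData(sub)[peak, s, , ])
model <- trainSelfSupervised(slices,
                             trainConfig(epochs = 10, seed = 7),
                             bsnConfig(), pdConfig(), verbose = TRUE)
#> epoch 1/10  L1 loss 1.26522
#> ...
#> epoch 10/10  L1 loss 0.16761

# PnP-BSN denoising and quantification
x  <- pnpDenoise(y, model, pnpConfig(rho = 1, nIters = 3))
attr(x, "residualHistory")      # ‖x − z‖ per ADMM iteration
#> [1] 2869.5351 1188.6470  769.4581
fd <- fdMap(computeMIP(seriesData(sub)[peak, , , ]), window = 11)
fd
#> FDMap: 64x64, window 11, scales {2,3,4,5,7}; FD range [2.000, 2.974]

seg <- kmeansSegment(y, lungMask(bundle)[6, , ], k = 3, seed = 1)
seg
#> SegmentationMap: 64x64, 3 classes; means 16.36, 56.72, 293.6
```

The segmentation means correspond to the low- (background parenchyma),
medium- (enhancing parenchyma) and high-intensity (vessel) classes; the FD
map quantifies perfusion texture complexity, with values near 2 in flat
regions and higher values over the vascular tree.

A constant image gives an FD map identically 2.0 (flat-surface baseline),
and on synthetic fractional Brownian surfaces the estimator recovers the
theoretical FD = 3 − H (validated in the test suite for
H ∈ {0.2, 0.5, 0.8}).

One full pipeline run (simulate → subtract → denoise → MIP → FD →
k-means → metrics) with on-disk intermediates and a JSON manifest:

```r
runPipeline(pipelineConfig(outDir = "run1", seed = 1,
                           denoiseMethod = "gaussian"))
```

A thin CLI over the same functions is in `inst/cli/perfusion.R`
(`simulate`, `preprocess`, `train`, `denoise`, `analyze`, `run`).

## Documentation

The methods vignette (`vignettes/perfusionBSN-methods.Rmd`) documents the
model, the estimator design and its validation, the phantom's scope and
limits, and all numerical choices.
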