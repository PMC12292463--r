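# Shared trained model for the end-to-end checks: trained once per test
# run (the most expensive fixture), on the peak-phase slices of two
# training phantoms; held-out evaluation uses a third phantom seed.

getTrainingSlices <- function(seeds = 1:2) {
  out <- list()
  for (sd in seeds) {
    b <- getPhantom(noiseSeed = sd)
    ps <- peakSlices(b, 2:11)
    out <- c(out, ps$noisy)
  }
  out
}

# Reduced network (default 32 channels, 4 dilated blocks), 35 epochs over
# 20 slices at batch 2 = 350 optimizer steps, 60-px patches.
getSharedModel <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$model <- trainSelfSupervised(
      getTrainingSlices(),
      trainConfig(epochs = 35L, batchSize = 2L, patchSize = 60L, seed = 7L),
      bsnConfig(), pdConfig())
  }
  .fixtures$model
}

getHeldOutPhantom <- function() getPhantom(noiseSeed = 33L)
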