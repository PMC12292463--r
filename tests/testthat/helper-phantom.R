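# Shared small fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Default phantom bundle (64x64, 12 slices, 6 frames), cached.
getPhantom <- function(noiseSeed = 1L, baseSigma = 20) {
  key <- sprintf("ph_%d_%g", noiseSeed, baseSigma)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulatePhantom(
      phantomSpec(), noiseSpec(baseSigma = baseSigma, seed = noiseSeed),
      seed = noiseSeed)
  .fixtures[[key]]
}

# Background-subtracted noisy + clean peak-phase slices of a bundle.
peakSlices <- function(bundle, slices = NULL) {
  sub <- backgroundSubtract(noisySeries(bundle), 1:2)
  csub <- backgroundSubtract(cleanSeries(bundle), 1:2)
  pk <- selectPeakFrame(sub, lungMask(bundle))
  if (is.null(slices)) slices <- seq_len(dim(sub@data)[2])
  list(noisy = lapply(slices, function(s) sub@data[pk, s, , ]),
       clean = lapply(slices, function(s) csub@data[pk, s, , ]),
       peak = pk, slices = slices)
}

# Tiny network configuration for structural tests.
tinyBSN <- function() bsnConfig(channels = 8L, nDilatedBlocks = 1L)
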