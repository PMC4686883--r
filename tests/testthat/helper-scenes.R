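# Shared phantom scene builders. The detector-floor noise model keeps the
# percentile normalization of the tip pipeline well defined when photon
# noise is off.

floorNoise <- list(type = "gaussian", readSigma = 2)

tipScene <- function(tip = c(137, 157.4, 112.3), approachAngle = 31,
                     seed = 1L, ...) {
  phantomSpec(tip = tip, approachAngle = approachAngle, noise = floorNoise,
              seed = seed, ...)
}

somaScene <- function(center = c(250, 157.4, 180), radius = 5, peak = 150,
                      noise = list(type = "none"), seed = 1L, ...) {
  phantomSpec(tip = c(137, 157.4, 112),
              cells = list(list(center = center, radius = radius,
                                peak = peak)),
              noise = noise, seed = seed, ...)
}

tipROI <- function(spec, center = tipPosition(spec@geometry),
                   half = c(25, 25, 20), seed = spec@seed) {
  renderStack(spec, region = list(center = center, halfExtent = half),
              seed = seed)$pipette
}

cellROI <- function(spec, center = spec@cells[[1L]]$center,
                    half = c(25, 25, 20), seed = spec@seed) {
  renderStack(spec, region = list(center = center, halfExtent = half),
              seed = seed)$cells
}

voxelUm <- c(1.23, 1.23, 2)
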