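# Shared fixture builders. Desk-scale simulations in unit tests use a
# reduced 64 x 64 lateral grid (full axial depth) to keep the suite fast;
# the acceptance tests run the default 192 x 192 grid.

small_config <- function(nx = 64, ny = nx, flow_scenario = "uniform") {
  cfg <- default_phantom_config(flow_scenario)
  cfg$grid$nx <- nx
  cfg$grid$ny <- ny
  cfg
}

# Minimal oct_volume wrapper around a list of amplitude arrays, for unit
# tests of the angiography operations that do not need a simulation.
fake_volume <- function(amps, pitch = 3, ilm = NULL, name = "SD840") {
  d <- dim(amps[[1]])
  if (is.null(ilm)) ilm <- matrix(d[3] * pitch, d[1], d[2])
  structure(list(
    amplitudes = amps,
    preset = device_preset(name, repeats = max(2L, length(amps))),
    axial_pitch = pitch, ilm = ilm, bm = NULL,
    provenance = list(seed = NA)
  ), class = "oct_volume")
}

# Rayleigh(scale) sampler via the modulus of a circular complex Gaussian.
rrayleigh <- function(n, scale) {
  sqrt(2) * scale * Mod(complex(real = stats::rnorm(n, 0, 1 / sqrt(2)),
                                imaginary = stats::rnorm(n, 0, 1 / sqrt(2))))
}

# Voxel mask of the choriocapillaris layer of a phantom (optionally only
# where the flow speed is positive).
cc_flow_mask <- function(phantom, require_flow = TRUE) {
  g <- phantom$grid
  zc <- (seq_len(g$nz) - 0.5) * g$axial_pitch
  out <- array(FALSE, c(g$nx, g$ny, g$nz))
  for (k in seq_len(g$nz)) {
    sl <- zc[k] >= phantom$bm & zc[k] < phantom$bm + phantom$cc_thickness
    if (require_flow) sl <- sl & phantom$flow_speed > 0
    out[, , k] <- sl
  }
  out
}
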