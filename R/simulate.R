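#' Depth-dependent detection sensitivity
#'
#' Amplitude sensitivity factor at depth z under the vitreoretinal protocol
#' (zero-delay at z = 0). Gaussian profile
#' `exp(-log(2) * (z / z6)^2)` where `z6` is the preset's 6-dB depth: the
#' factor is 1 at the zero-delay, 1/2 at `z6`, and identically 1 when
#' `z6 = Inf` (swept-source detection).
#'
#' @param preset `device_preset`.
#' @param z depth(s) in um, z >= 0.
#' @return sensitivity factor(s) in (0, 1].
#' @export
sensitivity <- function(preset, z) {
  stopifnot(all(z >= 0))
  z6 <- preset$rolloff_6db_um
  if (!is.finite(z6)) return(rep(1, length(z)))
  exp(-log(2) * (z / z6)^2)
}

# Attenuation coefficient (1/mm) per tissue at the preset wavelength.
mu_for_preset <- function(optics, preset) {
  col <- if (preset$center_wavelength_nm >= 1000) "attenuation_1050" else "attenuation_840"
  stats::setNames(optics[[col]], optics$tissue)
}

# One-way optical path (dimensionless, mu * length) from the top of the
# volume down to depth z for one lateral pixel, by exact overlap of [0, z]
# with the piecewise-constant tissue segments of that A-scan.
path_to_depth <- function(z, ilm, rpe, rpe_bot, bm, cc_bot, mu) {
  seg <- function(lo, hi) pmax(0, pmin(z, hi) - lo) * (z > lo)
  (mu[["retina"]] * seg(ilm, rpe) +
     mu[["RPE"]] * seg(rpe, rpe_bot) +
     mu[["druse"]] * seg(rpe_bot, bm) +
     mu[["choriocapillaris"]] * seg(bm, cc_bot) +
     mu[["choroid"]] * pmax(0, z - cc_bot)) / 1000
}

#' Round-trip Beer-Lambert attenuation factor
#'
#' `exp(-2 * integral_0^z mu(tissue) ds)` along the A-scan through (x, y),
#' with per-tissue attenuation coefficients taken at the preset wavelength
#' (the factor 2 accounts for the round trip). Monotone non-increasing in z.
#'
#' @param phantom `eye_phantom`.
#' @param preset `device_preset`.
#' @param x,y lateral position (mm).
#' @param z depth(s) in um.
#' @return attenuation factor(s) in (0, 1].
#' @export
attenuation_factor <- function(phantom, preset, x, y, z) {
  f <- phantom$field_mm
  if (x < 0 || x > f[1] || y < 0 || y > f[2]) stop("point outside the field")
  i <- pmin(phantom$grid$nx, pmax(1, ceiling(x / f[1] * phantom$grid$nx)))
  j <- pmin(phantom$grid$ny, pmax(1, ceiling(y / f[2] * phantom$grid$ny)))
  mu <- mu_for_preset(phantom$optics, preset)
  p <- path_to_depth(z, phantom$ilm[i, j], phantom$rpe[i, j],
                     phantom$rpe[i, j] + phantom$rpe_thickness,
                     phantom$bm[i, j], phantom$bm[i, j] + phantom$cc_thickness,
                     mu)
  exp(-2 * p)
}

# Noise-free mean amplitude mu_A = reflectivity * attenuation * sensitivity
# for every voxel, plus the per-voxel amplitude decorrelation target rho(v).
# Computed slice by slice to bound memory.
mean_amplitude_volume <- function(phantom, preset) {
  g <- phantom$grid
  mu <- mu_for_preset(phantom$optics, preset)
  refl <- stats::setNames(phantom$optics$reflectivity, phantom$optics$tissue)
  zc <- (seq_len(g$nz) - 0.5) * g$axial_pitch
  sens <- sensitivity(preset, zc)
  rpe_bot <- phantom$rpe + phantom$rpe_thickness
  cc_bot <- phantom$bm + phantom$cc_thickness
  amp <- array(0, c(g$nx, g$ny, g$nz))
  cc_mask <- array(FALSE, c(g$nx, g$ny, g$nz))
  for (k in seq_len(g$nz)) {
    z <- zc[k]
    lab_refl <- matrix(refl[["choroid"]], g$nx, g$ny)
    lab_refl[z < cc_bot] <- refl[["choriocapillaris"]]
    lab_refl[z < phantom$bm] <- refl[["druse"]]
    lab_refl[z < rpe_bot] <- refl[["RPE"]]
    lab_refl[z < phantom$rpe] <- refl[["retina"]]
    lab_refl[z < phantom$ilm] <- refl[["vitreous"]]
    p <- path_to_depth(z, phantom$ilm, phantom$rpe, rpe_bot,
                       phantom$bm, cc_bot, mu)
    amp[, , k] <- lab_refl * exp(-2 * p) * sens[k]
    cc_mask[, , k] <- z >= phantom$bm & z < cc_bot
  }
  list(amp = amp, cc_mask = cc_mask)
}

#' Simulate a repeated-B-scan OCT amplitude volume
#'
#' For each voxel the noise-free mean amplitude is
#' `reflectivity(tissue) * attenuation_factor * sensitivity(z)`. Repeats are
#' draws of fully developed speckle: each voxel-repeat amplitude is the
#' modulus of a circular complex Gaussian field, and flow decorrelates the
#' field between consecutive repeats so that the amplitude (envelope)
#' correlation across one interscan interval equals
#' `rho(v) = exp(-(v * dt / L_c)^2)` with `v` the local erythrocyte speed
#' (mm/s, nonzero only in the choriocapillaris layer), `dt` the preset
#' interscan time and `L_c = 10` um a decorrelation length constant. The
#' complex-field mixing coefficient is obtained by inverting the closed-form
#' envelope-correlation relation, so the stated rho is achieved on the
#' amplitudes themselves. The noise floor is additive in the complex field
#' (scale such that the noise-only amplitude is Rayleigh with scale
#' `noise_floor`), applied independently to every repeat; the vitreous is
#' pure noise. Static tissue with noise and speckle off yields bit-identical
#' repeats. Deterministic for fixed inputs and seed.
#'
#' @param phantom `eye_phantom`.
#' @param preset `device_preset`.
#' @param seed integer seed.
#' @param noise_on,speckle_on logical switches.
#' @param decorrelation_length_um speckle decorrelation length L_c (um).
#' @return object of class `oct_volume` with fields `amplitudes` (list of R
#'   `nx x ny x nz` arrays), `preset`, `axial_pitch`, `ilm`, `bm` (ground
#'   truth surfaces for downstream defaults) and `provenance`.
#' @export
simulate_volume <- function(phantom, preset, seed = 1L, noise_on = TRUE,
                            speckle_on = TRUE, decorrelation_length_um = 10) {
  if (preset$repeats < 2) stop("OCTA requires at least 2 repeated B-scans")
  validate_optics(phantom$optics)
  g <- phantom$grid
  nvox <- g$nx * g$ny * g$nz
  base <- mean_amplitude_volume(phantom, preset)
  mu_amp <- base$amp

  # Per-voxel field mixing coefficient between consecutive repeats.
  speeds <- unique(as.vector(phantom$flow_speed))
  ratio <- speeds * preset$interscan_ms / decorrelation_length_um  # v[mm/s]*dt[ms] = um
  rho_amp <- exp(-ratio^2)
  a_by_speed <- stats::setNames(field_coefficient(rho_amp), format(speeds, digits = 15))
  a <- array(1, c(g$nx, g$ny, g$nz))
  speed_vol <- array(0, c(g$nx, g$ny, g$nz))
  for (k in seq_len(g$nz)) {
    sl <- base$cc_mask[, , k]
    if (any(sl)) {
      sv <- matrix(0, g$nx, g$ny)
      sv[sl] <- phantom$flow_speed[sl]
      speed_vol[, , k] <- sv
    }
  }
  for (s in seq_along(speeds)) {
    if (speeds[s] > 0) a[speed_vol == speeds[s] & base$cc_mask] <-
        a_by_speed[[format(speeds[s], digits = 15)]]
  }

  mean_env <- sqrt(pi) / 2       # E|g| for g ~ CN(0,1)
  b <- mu_amp / mean_env         # signal field scale so E|amplitude| = mu_amp
  nu <- preset$noise_floor * sqrt(2)  # complex noise scale -> Rayleigh(noise_floor)

  set.seed(as.integer(seed))
  amps <- vector("list", preset$repeats)
  cn <- function(m = nvox) complex(real = stats::rnorm(m, 0, 1 / sqrt(2)),
                                   imaginary = stats::rnorm(m, 0, 1 / sqrt(2)))
  if (speckle_on) {
    gfield <- cn()
    # only flowing voxels (a < 1) draw an innovation between repeats; static
    # speckle carries over unchanged, so the AR(1) update is applied sparsely
    flow_idx <- which(a < 1)
    af <- a[flow_idx]
    mix <- sqrt(1 - af^2)
    for (n in seq_len(preset$repeats)) {
      if (n > 1 && length(flow_idx) > 0) {
        gfield[flow_idx] <- af * gfield[flow_idx] + mix * cn(length(flow_idx))
      }
      field <- b * gfield
      if (noise_on) field <- field + nu * cn()
      amps[[n]] <- array(Mod(field), c(g$nx, g$ny, g$nz))
    }
  } else {
    for (n in seq_len(preset$repeats)) {
      field <- mu_amp
      if (noise_on) field <- field + nu * cn()
      amps[[n]] <- array(Mod(field), c(g$nx, g$ny, g$nz))
    }
  }

  structure(list(
    amplitudes = amps, preset = preset, axial_pitch = g$axial_pitch,
    ilm = phantom$ilm, bm = phantom$bm,
    provenance = list(seed = as.integer(seed), noise_on = noise_on,
                      speckle_on = speckle_on,
                      decorrelation_length_um = decorrelation_length_um,
                      field_mm = phantom$field_mm)
  ), class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$amplitudes[[1]])
  cat("<oct_volume> ", x$preset$name, ", ", length(x$amplitudes),
      " repeats, grid ", d[1], "x", d[2], "x", d[3],
      " (axial pitch ", x$axial_pitch, " um)\n", sep = "")
  invisible(x)
}

#' Mean OCT amplitude over repeats
#'
#' @param volume `oct_volume`.
#' @return `nx x ny x nz` array.
#' @export
mean_oct <- function(volume) {
  Reduce(`+`, volume$amplitudes) / length(volume$amplitudes)
}
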