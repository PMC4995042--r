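#' OCTA device acquisition presets
#'
#' Acquisition physics and geometry of the two devices compared by the
#' pipeline:
#'
#' * `SD840` — a commercial spectral-domain system: ~840 nm center
#'   wavelength, 70,000 A-scans/s, two repeated B-scans at each of 304
#'   uniformly spaced locations (304 A-scans each), ~5 ms interscan time,
#'   ~5 um axial resolution. Spectrometer-based detection suffers
#'   sensitivity roll-off with depth; modeled as a Gaussian sensitivity
#'   profile with a 6-dB (half-amplitude) depth of 600 um.
#' * `SS1050` — a swept-source prototype: ~1050 nm, 400,000 A-scans/s, five
#'   repeated B-scans at each of 500 locations (500 A-scans each), ~1.5 ms
#'   interscan time, ~8-9 um axial resolution. Swept-source detection has
#'   negligible roll-off over the retinal depth range; modeled as infinite
#'   6-dB depth.
#'
#' Both presets share an additive noise floor of Rayleigh scale 0.02 in
#' normalized amplitude units. Fields can be overridden via `...` (e.g. a
#' custom `rolloff_6db_um`). The native lateral grids (`n_locations`,
#' `n_ascans`) are carried as metadata; simulation runs on the phantom grid.
#'
#' @param name `"SD840"` or `"SS1050"`.
#' @param ... named overrides of preset fields.
#' @return object of class `device_preset`.
#' @export
device_preset <- function(name = c("SD840", "SS1050"), ...) {
  name <- match.arg(name)
  p <- if (name == "SD840") {
    list(name = "SD840", center_wavelength_nm = 840, ascan_rate = 70000,
         repeats = 2L, n_locations = 304L, n_ascans = 304L,
         interscan_ms = 5, axial_resolution_um = 5,
         rolloff_6db_um = 600, noise_floor = 0.02)
  } else {
    list(name = "SS1050", center_wavelength_nm = 1050, ascan_rate = 400000,
         repeats = 5L, n_locations = 500L, n_ascans = 500L,
         interscan_ms = 1.5, axial_resolution_um = 8.5,
         rolloff_6db_um = Inf, noise_floor = 0.02)
    }
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(p)) stop("unknown preset field: ", nm)
    p[[nm]] <- over[[nm]]
  }
  if (p$repeats < 2) stop("OCTA requires at least 2 repeated B-scans")
  if (p$noise_floor < 0) stop("noise_floor must be >= 0")
  structure(p, class = "device_preset")
}

#' @export
print.device_preset <- function(x, ...) {
  cat("<device_preset> ", x$name, ": ", x$center_wavelength_nm, " nm, R = ",
      x$repeats, ", dt = ", x$interscan_ms, " ms, 6-dB roll-off depth ",
      x$rolloff_6db_um, " um\n", sep = "")
  invisible(x)
}
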