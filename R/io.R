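# Volume and image I/O: multi-page 32-bit float TIFF stacks (pages = depth
# slices) with a JSON metadata sidecar. Data are rescaled into [0, 1] by a
# recorded maximum before writing, so the round trip is exact to 32-bit
# float precision.

write_float_stack <- function(arr, path) {
  mx <- max(arr, 1e-300)
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  mx
}

read_float_stack <- function(path, scale) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr * scale
}

#' Write an OCT volume to TIFF + JSON sidecar
#'
#' One multi-page float TIFF per repeat plus `<basename>.json` carrying the
#' preset, axial pitch, per-repeat scale factors and provenance.
#'
#' @param volume `oct_volume`.
#' @param dir output directory (created if missing).
#' @param basename file stem.
#' @return invisibly, the sidecar path.
#' @export
write_oct_volume <- function(volume, dir, basename = "oct_volume") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  scales <- numeric(0)
  for (n in seq_along(volume$amplitudes)) {
    f <- file.path(dir, sprintf("%s_repeat%02d.tif", basename, n))
    scales[n] <- write_float_stack(volume$amplitudes[[n]], f)
    files[n] <- basename(f)
  }
  sidecar <- file.path(dir, paste0(basename, ".json"))
  jsonlite::write_json(list(
    kind = "oct_volume", preset = unclass(volume$preset),
    axial_pitch = volume$axial_pitch, repeat_files = files,
    scales = scales, ilm = as.vector(volume$ilm[1, 1]),
    dim = dim(volume$amplitudes[[1]]),
    provenance = volume$provenance
  ), sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sidecar)
}

#' Read an OCT volume written by [write_oct_volume()]
#'
#' @param sidecar path to the JSON sidecar.
#' @return `oct_volume` (ILM surface restored as a constant plane; BM is not
#'   carried through disk round trips and must be re-supplied for slabs).
#' @export
read_oct_volume <- function(sidecar) {
  meta <- jsonlite::fromJSON(sidecar)
  dir <- dirname(sidecar)
  amps <- lapply(seq_along(meta$repeat_files), function(n) {
    read_float_stack(file.path(dir, meta$repeat_files[n]), meta$scales[n])
  })
  preset <- structure(as.list(meta$preset), class = "device_preset")
  if (is.null(preset$rolloff_6db_um) || !is.finite(preset$rolloff_6db_um)) {
    preset$rolloff_6db_um <- Inf
  }
  structure(list(
    amplitudes = amps, preset = preset, axial_pitch = meta$axial_pitch,
    ilm = matrix(meta$ilm, meta$dim[1], meta$dim[2]), bm = NULL,
    provenance = meta$provenance
  ), class = "oct_volume")
}

#' Write an OCTA volume to TIFF + JSON sidecar
#'
#' Thresholded decorrelation as a 32-bit float multi-page TIFF, the
#' below-threshold mask as an 8-bit TIFF, and the noise statistics plus
#' provenance in the sidecar.
#'
#' @param octa `octa_volume`.
#' @param dir output directory.
#' @param basename file stem.
#' @return invisibly, the sidecar path.
#' @export
write_octa_volume <- function(octa, dir, basename = "octa_volume") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_d <- file.path(dir, paste0(basename, "_decorr.tif"))
  f_m <- file.path(dir, paste0(basename, "_mask.tif"))
  f_oct <- file.path(dir, paste0(basename, "_meanoct.tif"))
  s_d <- write_float_stack(octa$D, f_d)
  s_oct <- write_float_stack(octa$mean_oct, f_oct)
  mask_pages <- lapply(seq_len(dim(octa$D)[3]),
                       function(k) octa$mask_below_threshold[, , k] + 0)
  tiff::writeTIFF(mask_pages, f_m, bits.per.sample = 8L)
  sidecar <- file.path(dir, paste0(basename, ".json"))
  jsonlite::write_json(list(
    kind = "octa_volume", device = octa$preset$name,
    axial_pitch = octa$axial_pitch,
    noise = unclass(octa$noise),
    files = list(decorr = basename(f_d), mask = basename(f_m),
                 meanoct = basename(f_oct)),
    scales = list(decorr = s_d, meanoct = s_oct),
    provenance = octa$provenance
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read an OCTA volume written by [write_octa_volume()]
#'
#' @param sidecar path to the JSON sidecar.
#' @return `octa_volume` (without BM/ILM surfaces; re-supply from the
#'   phantom for slab projection).
#' @export
read_octa_volume <- function(sidecar) {
  meta <- jsonlite::fromJSON(sidecar)
  dir <- dirname(sidecar)
  D <- read_float_stack(file.path(dir, meta$files$decorr), meta$scales$decorr)
  m <- read_float_stack(file.path(dir, meta$files$mask), 1) > 0.5
  mo <- read_float_stack(file.path(dir, meta$files$meanoct), meta$scales$meanoct)
  structure(list(
    D = D, mask_below_threshold = m,
    noise = structure(as.list(meta$noise), class = "noise_stats"),
    mean_oct = mo,
    preset = device_preset(meta$device),
    axial_pitch = meta$axial_pitch, provenance = meta$provenance
  ), class = "octa_volume")
}

#' Export phantom ground truth for inspection
#'
#' Geometry and drusen table as JSON, plus the lateral flow-speed map as a
#' float TIFF.
#'
#' @param phantom `eye_phantom`.
#' @param dir output directory.
#' @param basename file stem.
#' @return invisibly, the JSON path.
#' @export
export_phantom <- function(phantom, dir, basename = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_flow <- file.path(dir, paste0(basename, "_flow.tif"))
  s_flow <- write_float_stack(array(phantom$flow_speed,
                                    c(dim(phantom$flow_speed), 1)), f_flow)
  f_json <- file.path(dir, paste0(basename, ".json"))
  jsonlite::write_json(list(
    kind = "eye_phantom", field_mm = phantom$field_mm, grid = phantom$grid,
    layers = phantom$config$layers, drusen = phantom$drusen,
    flow = list(scenario = phantom$flow$scenario, speed = phantom$flow$speed,
                map_file = basename(f_flow), map_scale = s_flow),
    optics = phantom$optics, seed = phantom$seed
  ), f_json, auto_unbox = TRUE, digits = NA)
  invisible(f_json)
}

#' Write an en face pair to TIFF + JSON sidecar
#'
#' @param pair `enface_pair`.
#' @param dir output directory.
#' @param basename file stem.
#' @return invisibly, the sidecar path.
#' @export
write_enface_pair <- function(pair, dir, basename = "enface") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  to3d <- function(m) array(m, c(dim(m), 1))
  f_oct <- file.path(dir, paste0(basename, "_oct.tif"))
  f_octa <- file.path(dir, paste0(basename, "_octa.tif"))
  f_mask <- file.path(dir, paste0(basename, "_maskfrac.tif"))
  s_oct <- write_float_stack(to3d(pair$oct_slab), f_oct)
  s_octa <- write_float_stack(to3d(pair$octa_slab), f_octa)
  s_mask <- write_float_stack(to3d(pair$masked_fraction), f_mask)
  sidecar <- file.path(dir, paste0(basename, ".json"))
  jsonlite::write_json(list(
    kind = "enface_pair", device = pair$device, spec = unclass(pair$spec),
    files = list(oct = basename(f_oct), octa = basename(f_octa),
                 maskfrac = basename(f_mask)),
    scales = list(oct = s_oct, octa = s_octa, maskfrac = s_mask)
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read an en face pair written by [write_enface_pair()]
#'
#' @param sidecar path to the JSON sidecar.
#' @return `enface_pair`.
#' @export
read_enface_pair <- function(sidecar) {
  meta <- jsonlite::fromJSON(sidecar)
  dir <- dirname(sidecar)
  rd <- function(which) {
    read_float_stack(file.path(dir, meta$files[[which]]),
                     meta$scales[[which]])[, , 1]
  }
  spec <- structure(as.list(meta$spec), class = "slab_spec")
  structure(list(oct_slab = rd("oct"), octa_slab = rd("octa"),
                 masked_fraction = rd("maskfrac"), spec = spec,
                 device = meta$device),
            class = "enface_pair")
}

#' Write per-druse grades and cohort summary CSVs
#'
#' @param graded result of [grade_cohort()] or [run_study()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the two file paths.
#' @export
write_grades <- function(graded, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, paste0(prefix, "_grades.csv"))
  utils::write.csv(graded$grades, f1, row.names = FALSE)
  f2 <- file.path(dir, paste0(prefix, "_summary.csv"))
  utils::write.csv(summary_as_data_frame(graded$summary), f2, row.names = FALSE)
  invisible(c(grades = f1, summary = f2))
}

#' Cohort summary as a flat data.frame
#'
#' @param summary `cohort_summary`.
#' @return data.frame with one row per device.
#' @export
summary_as_data_frame <- function(summary) {
  row <- function(dev, s) {
    data.frame(device = dev, n_drusen = summary$n_drusen,
               n_loss = s$n_loss, pct_loss = s$pct_loss,
               n_ambiguous = s$n_ambiguous, pct_ambiguous = s$pct_ambiguous,
               n_unambiguous = s$n_unambiguous,
               pct_unambiguous = s$pct_unambiguous,
               n_false_positive = s$n_false_positive,
               pct_false_positive = s$pct_false_positive,
               stringsAsFactors = FALSE)
  }
  rbind(row("SD840", summary$sd), row("SS1050", summary$ss))
}

#' Render a cohort summary as human-readable text
#'
#' One line per device in the shape of the study's results narrative, e.g.
#' `"SD840: 17/23 (73.9%) OCTA signal loss; 14 ambiguous (82.4%), 3
#' unambiguous (17.6%); 10 false-positive flow impairment (58.8%)"`.
#'
#' @param summary `cohort_summary`.
#' @return character vector of lines.
#' @export
render_summary_text <- function(summary) {
  if (summary$n_drusen == 0) {
    return("Zero drusen analyzed.")
  }
  fmt <- function(dev, s) {
    sprintf(paste0("%s: %d/%d (%.1f%%) OCTA signal loss; %d ambiguous (%s), ",
                   "%d unambiguous (%s); %d false-positive flow impairment (%s)"),
            dev, s$n_loss, summary$n_drusen, s$pct_loss,
            s$n_ambiguous, pct_str(s$pct_ambiguous),
            s$n_unambiguous, pct_str(s$pct_unambiguous),
            s$n_false_positive, pct_str(s$pct_false_positive))
  }
  c(sprintf("Drusen analyzed: %d", summary$n_drusen),
    fmt("SD840", summary$sd), fmt("SS1050", summary$ss))
}

pct_str <- function(p) if (is.na(p)) "-" else sprintf("%.1f%%", p)
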