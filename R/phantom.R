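#' Default per-tissue optical properties
#'
#' Backscatter reflectivity (dimensionless amplitude coefficient) and
#' attenuation coefficients (1/mm) at the two device wavelengths for each
#' tissue class. The table encodes the key wavelength asymmetry: the RPE and
#' druse material attenuate 840-nm light much more strongly than 1050-nm
#' light, so the round-trip amplitude loss under a large druse is severe
#' (> 6 dB) at 840 nm and mild at 1050 nm. All values are configurable.
#'
#' @return data.frame with columns `tissue`, `reflectivity`,
#'   `attenuation_840`, `attenuation_1050`.
#' @export
default_optics <- function() {
  data.frame(
    tissue = c("vitreous", "retina", "RPE", "druse", "choriocapillaris", "choroid"),
    reflectivity = c(0, 0.2, 1.0, 0.4, 0.6, 0.5),
    attenuation_840 = c(0, 1.0, 12.0, 12.0, 2.0, 2.0),
    attenuation_1050 = c(0, 0.8, 3.0, 2.0, 1.5, 1.5),
    stringsAsFactors = FALSE
  )
}

validate_optics <- function(optics) {
  needed <- c("tissue", "reflectivity", "attenuation_840", "attenuation_1050")
  if (!all(needed %in% names(optics))) {
    stop("optics table must have columns: ", paste(needed, collapse = ", "))
  }
  num <- unlist(optics[c("reflectivity", "attenuation_840", "attenuation_1050")])
  if (any(!is.finite(num)) || any(num < 0)) {
    stop("optical coefficients must be finite and non-negative")
  }
  for (tt in c("RPE", "druse")) {
    row <- optics[optics$tissue == tt, ]
    if (nrow(row) == 1 && row$attenuation_840 < row$attenuation_1050) {
      stop("attenuation at 840 nm must be >= attenuation at 1050 nm for ", tt)
    }
  }
  invisible(optics)
}

#' Default phantom configuration
#'
#' Desk-scale digital macular phantom: a 3 x 3 mm field on a 192 x 192
#' lateral grid with 320 axial samples at 3 um pitch (960 um depth range),
#' imaged under the vitreoretinal protocol (zero-delay at the top of the
#' B-scan, depth increasing downward). The retina sits deep in the scan, as
#' it does clinically when the vitreous occupies the top of the frame, which
#' places the choriocapillaris where spectrometer-based sensitivity roll-off
#' is substantial. Default drusen: three analysis-eligible soft drusen
#' (diameter >= 165 um) plus one small ineligible druse; heights fall in the
#' 60-120 um range typical of large soft drusen. Flow is uniform at 2 mm/s
#' in the choriocapillaris layer unless a void scenario is selected.
#'
#' @param flow_scenario one of `"uniform"`, `"voids_under_drusen"`,
#'   `"voids_elsewhere"`.
#' @return nested list accepted by [make_phantom()].
#' @export
default_phantom_config <- function(flow_scenario = "uniform") {
  list(
    field_mm = c(3, 3),
    grid = list(nx = 192, ny = 192, nz = 320, axial_pitch = 3),
    layers = list(ilm = 540, bm = 760, rpe_thickness = 15, cc_thickness = 60),
    drusen = list(
      list(center = c(0.80, 0.80), diameter = 300, height = 120),
      list(center = c(2.10, 1.00), diameter = 250, height = 105),
      list(center = c(1.00, 2.20), diameter = 220, height = 90),
      list(center = c(2.25, 2.25), diameter = 160, height = 45)
    ),
    flow = list(
      scenario = flow_scenario,
      speed = 2,
      void_regions = list(list(center = c(1.6, 1.6), diameter = 250))
    ),
    optics = default_optics()
  )
}

#' Read a phantom configuration from YAML or JSON
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return configuration list (optics coerced to data.frame).
#' @export
read_phantom_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  if (!is.null(cfg$optics)) cfg$optics <- as.data.frame(cfg$optics)
  if (is.list(cfg$field_mm)) cfg$field_mm <- unlist(cfg$field_mm)
  cfg
}

#' Disable tissue attenuation in a configuration
#'
#' Returns a copy of the configuration with every attenuation coefficient set
#' to zero (reflectivity and geometry untouched). Used to separate the
#' shadowing artifact from true flow deficits in controlled experiments.
#'
#' @param config phantom configuration list.
#' @return modified configuration.
#' @export
disable_attenuation <- function(config) {
  config$optics$attenuation_840 <- 0 * config$optics$attenuation_840
  config$optics$attenuation_1050 <- 0 * config$optics$attenuation_1050
  config
}

# Parabolic dome: height * max(0, 1 - (2 r / diameter)^2), r in um.
druse_profile <- function(r, diameter, height, shape = "parabolic") {
  u <- (2 * r / diameter)^2
  if (shape == "gaussian") {
    # Gaussian with the same full width at zero ~ 2 sigma at the rim
    height * exp(-2 * u) * (u < 1)
  } else {
    height * pmax(0, 1 - u)
  }
}

#' Build a ground-truth eye phantom
#'
#' Constructs the layered macular phantom the simulator consumes: lateral
#' surface-depth fields for the ILM, RPE and Bruch's membrane (BM, planar by
#' default), dome-shaped drusen that lift the RPE off BM, a thin
#' choriocapillaris flow layer immediately below BM, and the optics table.
#' Depth z (um) increases away from the instrument with z = 0 at the top of
#' the B-scan.
#'
#' @param config configuration list, see [default_phantom_config()].
#' @param seed integer seed (construction is deterministic; the seed is
#'   recorded for provenance and reserved for randomized cohort configs).
#' @return object of class `eye_phantom`.
#' @export
make_phantom <- function(config = default_phantom_config(), seed = 1L) {
  g <- config$grid
  field <- config$field_mm
  stopifnot(length(field) == 2, all(field > 0),
            g$nx >= 1, g$ny >= 1, g$nz >= 1, g$axial_pitch > 0)
  lay <- config$layers
  if (lay$ilm <= 0 || lay$bm <= lay$ilm || lay$rpe_thickness <= 0 ||
      lay$cc_thickness <= 0) {
    stop("negative or inverted layer geometry")
  }
  if (lay$bm + lay$cc_thickness >= g$nz * g$axial_pitch) {
    stop("choriocapillaris layer exits the axial range")
  }
  validate_optics(config$optics)

  xs <- pixel_centers(g$nx, field[1])
  ys <- pixel_centers(g$ny, field[2])

  drusen_in <- normalize_drusen(config$drusen)
  drusen <- do.call(rbind, lapply(seq_along(drusen_in), function(i) {
    d <- drusen_in[[i]]
    data.frame(id = i, center_x = d$center[1], center_y = d$center[2],
               diameter = d$diameter, height = d$height,
               shape = if (is.null(d$shape)) "parabolic" else d$shape,
               stringsAsFactors = FALSE)
  }))
  if (is.null(drusen)) {
    drusen <- data.frame(id = integer(), center_x = numeric(),
                         center_y = numeric(), diameter = numeric(),
                         height = numeric(), shape = character())
  }
  if (nrow(drusen) > 0) {
    if (any(drusen$diameter <= 0) || any(drusen$height <= 0)) {
      stop("negative geometry: druse diameter and height must be positive")
    }
    r_mm <- drusen$diameter / 2000
    inside <- drusen$center_x - r_mm >= 0 & drusen$center_x + r_mm <= field[1] &
      drusen$center_y - r_mm >= 0 & drusen$center_y + r_mm <= field[2]
    if (!all(inside)) {
      stop("druse footprint leaves the ", field[1], " x ", field[2], " mm field")
    }
    drusen$eligible <- drusen$diameter >= 165
  } else {
    drusen$eligible <- logical()
  }

  # RPE elevation above its resting position: max of all druse profiles
  elevation <- matrix(0, g$nx, g$ny)
  for (i in seq_len(nrow(drusen))) {
    dx <- (xs - drusen$center_x[i]) * 1000
    dy <- (ys - drusen$center_y[i]) * 1000
    r <- sqrt(outer(dx^2, dy^2, `+`))
    elevation <- pmax(elevation,
                      druse_profile(r, drusen$diameter[i], drusen$height[i],
                                    drusen$shape[i]))
  }

  bm <- matrix(lay$bm, g$nx, g$ny)
  rpe <- bm - lay$rpe_thickness - elevation
  ilm <- matrix(lay$ilm, g$nx, g$ny)
  if (any(ilm >= rpe)) stop("druse elevation reaches the ILM; reduce height")

  flow_speed <- flow_speed_map(config, xs, ys, drusen)

  structure(list(
    field_mm = field, grid = g,
    ilm = ilm, rpe = rpe, bm = bm, elevation = elevation,
    rpe_thickness = lay$rpe_thickness, cc_thickness = lay$cc_thickness,
    drusen = drusen, flow_speed = flow_speed, flow = config$flow,
    optics = config$optics, config = config, seed = as.integer(seed)
  ), class = "eye_phantom")
}

# Accept drusen either as a list of lists (native configs) or as the
# data.frame a JSON round trip produces.
normalize_drusen <- function(dr) {
  if (is.null(dr)) return(list())
  if (is.data.frame(dr)) {
    return(lapply(seq_len(nrow(dr)), function(i) {
      ctr <- dr$center
      c0 <- if (is.matrix(ctr)) ctr[i, ] else if (is.list(ctr)) unlist(ctr[[i]])
            else c(dr$center_x[i], dr$center_y[i])
      out <- list(center = as.numeric(c0), diameter = dr$diameter[i],
                  height = dr$height[i])
      if ("shape" %in% names(dr)) out$shape <- dr$shape[i]
      out
    }))
  }
  dr
}

flow_speed_map <- function(config, xs, ys, drusen) {
  fl <- config$flow
  v <- matrix(fl$speed, length(xs), length(ys))
  zero_disc <- function(v, cx, cy, diameter) {
    dx <- (xs - cx) * 1000
    dy <- (ys - cy) * 1000
    v[sqrt(outer(dx^2, dy^2, `+`)) < diameter / 2] <- 0
    v
  }
  if (identical(fl$scenario, "voids_under_drusen")) {
    for (i in seq_len(nrow(drusen))) {
      v <- zero_disc(v, drusen$center_x[i], drusen$center_y[i], drusen$diameter[i])
    }
  } else if (identical(fl$scenario, "voids_elsewhere")) {
    for (vr in fl$void_regions) {
      v <- zero_disc(v, vr$center[1], vr$center[2], vr$diameter)
    }
  } else if (!identical(fl$scenario, "uniform")) {
    stop("unknown flow scenario: ", fl$scenario)
  }
  v
}

#' @export
print.eye_phantom <- function(x, ...) {
  cat("<eye_phantom> ", x$field_mm[1], "x", x$field_mm[2], "mm, grid ",
      x$grid$nx, "x", x$grid$ny, "x", x$grid$nz,
      " (axial pitch ", x$grid$axial_pitch, " um)\n", sep = "")
  cat("  drusen: ", nrow(x$drusen), " (", sum(x$drusen$eligible),
      " eligible >= 165 um), flow: ", x$flow$scenario, "\n", sep = "")
  invisible(x)
}

#' Tissue label at a point
#'
#' Resolves the tissue class at lateral position (x, y) mm and depth z um by
#' the depth ordering vitreous, retina, RPE, druse (between the elevated RPE
#' and BM inside a footprint), choriocapillaris (BM to BM + cc_thickness),
#' choroid. Vectorized over `z`.
#'
#' @param phantom `eye_phantom`.
#' @param x,y lateral position in mm.
#' @param z depth(s) in um, z >= 0.
#' @return character vector of tissue labels.
#' @export
tissue_at <- function(phantom, x, y, z) {
  f <- phantom$field_mm
  if (x < 0 || x > f[1] || y < 0 || y > f[2]) {
    stop("query point outside the ", f[1], " x ", f[2], " mm field")
  }
  stopifnot(all(z >= 0))
  i <- pmin(phantom$grid$nx, pmax(1, ceiling(x / f[1] * phantom$grid$nx)))
  j <- pmin(phantom$grid$ny, pmax(1, ceiling(y / f[2] * phantom$grid$ny)))
  ilm <- phantom$ilm[i, j]; rpe <- phantom$rpe[i, j]; bm <- phantom$bm[i, j]
  rpe_bot <- rpe + phantom$rpe_thickness
  cc_bot <- bm + phantom$cc_thickness
  out <- rep("choroid", length(z))
  out[z < cc_bot] <- "choriocapillaris"
  out[z < bm] <- "druse"
  out[z < rpe_bot] <- "RPE"
  out[z < rpe] <- "retina"
  out[z < ilm] <- "vitreous"
  out
}

#' Analysis-eligible drusen
#'
#' Filters the phantom's drusen to those meeting the large soft druse
#' criterion, lateral diameter >= 165 um (boundary inclusive), preserving
#' order.
#'
#' @param phantom `eye_phantom`.
#' @return data.frame subset of `phantom$drusen`.
#' @export
eligible_drusen <- function(phantom) {
  phantom$drusen[phantom$drusen$diameter >= 165, , drop = FALSE]
}

#' Lateral footprint mask of a druse
#'
#' Boolean mask of lateral pixels whose centers lie within the druse
#' footprint disc, on the phantom grid or a caller-supplied grid.
#'
#' @param phantom `eye_phantom`.
#' @param druse one row of `phantom$drusen` (or a list with `center_x`,
#'   `center_y`, `diameter`).
#' @param grid optional list with `nx`, `ny` (defaults to the phantom grid).
#' @return logical `nx x ny` matrix.
#' @export
druse_roi <- function(phantom, druse, grid = phantom$grid) {
  if (is.null(grid$nx) || is.null(grid$ny) || grid$nx < 1 || grid$ny < 1) {
    stop("grid with zero pixels")
  }
  xs <- pixel_centers(grid$nx, phantom$field_mm[1])
  ys <- pixel_centers(grid$ny, phantom$field_mm[2])
  dx <- (xs - druse$center_x) * 1000
  dy <- (ys - druse$center_y) * 1000
  sqrt(outer(dx^2, dy^2, `+`)) < druse$diameter / 2
}

#' Lateral mask of the pure-vitreous region of a volume grid
#'
#' Voxel mask (same dimensions as the simulated volume) of depths at least
#' two axial pixels above the ILM; this region carries no tissue signal and
#' serves as the default noise-estimation region.
#'
#' @param phantom `eye_phantom`.
#' @param margin_px axial pixels of clearance below the mask, above the ILM.
#' @return logical `nx x ny x nz` array.
#' @export
vitreous_mask <- function(phantom, margin_px = 2) {
  g <- phantom$grid
  zc <- (seq_len(g$nz) - 0.5) * g$axial_pitch
  lim <- phantom$ilm - margin_px * g$axial_pitch
  out <- array(FALSE, c(g$nx, g$ny, g$nz))
  for (k in seq_len(g$nz)) out[, , k] <- zc[k] < lim
  out
}
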