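#' Pairwise amplitude decorrelation
#'
#' Computes the raw decorrelation field from the repeated B-scans, as an
#' unsplit single-spectrum version of the pairwise intensity decorrelation
#' used in amplitude-decorrelation angiography:
#' \deqn{D = 1 - \frac{1}{R-1} \sum_{n=1}^{R-1}
#'       \frac{A_n A_{n+1}}{\tfrac12 (A_n^2 + A_{n+1}^2)}}
#' By the AM-GM inequality every pair term lies in [0, 1], hence so does D.
#' A pair with both amplitudes exactly zero contributes decorrelation 0
#' (empty signal must not fabricate flow; such voxels are masked downstream
#' anyway).
#'
#' @param volume `oct_volume` with R >= 2 non-negative amplitude repeats.
#' @return `nx x ny x nz` array of decorrelation values in [0, 1].
#' @export
decorrelate <- function(volume) {
  amps <- volume$amplitudes
  R <- length(amps)
  if (R < 2) stop("decorrelation requires at least 2 repeated B-scans")
  if (any(vapply(amps, function(a) any(a < 0), logical(1)))) {
    stop("negative amplitude in OCT volume")
  }
  acc <- 0
  for (n in seq_len(R - 1)) {
    a1 <- amps[[n]]; a2 <- amps[[n + 1]]
    denom <- 0.5 * (a1 * a1 + a2 * a2)
    term <- (a1 * a2) / denom
    term[denom == 0] <- 1   # 0/0 pair: decorrelation contribution 0
    acc <- acc + term
  }
  D <- 1 - acc / (R - 1)
  D[D < 0] <- 0
  D[D > 1] <- 1
  D
}

#' Estimate the noise level and OCTA threshold
#'
#' Sample mean and standard deviation of the mean-over-repeats OCT amplitude
#' in a signal-free region, and the threshold set 2 standard deviations
#' above the noise mean.
#'
#' @param volume `oct_volume`.
#' @param noise_region logical array (same voxel grid) marking the
#'   noise-estimation region; defaults to the vitreous (all voxels at least
#'   two axial pixels above the ILM).
#' @return object of class `noise_stats` with `mean`, `sd`, `threshold`,
#'   `n_voxels`, `region`.
#' @export
estimate_noise <- function(volume, noise_region = NULL) {
  region_desc <- "caller-supplied mask"
  if (is.null(noise_region)) {
    zc <- (seq_len(dim(volume$amplitudes[[1]])[3]) - 0.5) * volume$axial_pitch
    lim <- volume$ilm - 2 * volume$axial_pitch
    noise_region <- array(FALSE, dim(volume$amplitudes[[1]]))
    for (k in seq_along(zc)) noise_region[, , k] <- zc[k] < lim
    region_desc <- "vitreous, 2 axial px above ILM"
  }
  vals <- mean_oct(volume)[noise_region]
  if (length(vals) == 0) stop("empty noise-estimation region")
  mu <- mean(vals)
  sdv <- if (length(vals) > 1) stats::sd(vals) else 0
  structure(list(mean = mu, sd = sdv, threshold = mu + 2 * sdv,
                 n_voxels = length(vals), region = region_desc),
            class = "noise_stats")
}

#' @export
print.noise_stats <- function(x, ...) {
  cat(sprintf("<noise_stats> mean %.4g, sd %.4g, threshold %.4g (%d voxels; %s)\n",
              x$mean, x$sd, x$threshold, x$n_voxels, x$region))
  invisible(x)
}

#' Apply OCT-signal thresholding to a decorrelation field
#'
#' OCTA voxels whose mean OCT amplitude falls below the threshold are set to
#' zero and recorded in the mask; the comparison is strict (a voxel exactly
#' at the threshold is retained). This is the step that makes low-signal and
#' low-flow regions indistinguishable in the thresholded output.
#'
#' @param D raw decorrelation array.
#' @param mean_oct per-voxel mean amplitude array, congruent with `D`.
#' @param noise `noise_stats`.
#' @return object of class `octa_volume` with `D` (thresholded),
#'   `mask_below_threshold`, `noise`, `mean_oct`.
#' @export
apply_threshold <- function(D, mean_oct, noise) {
  if (!identical(dim(D), dim(mean_oct))) {
    stop("decorrelation and mean OCT grids do not match")
  }
  mask <- mean_oct < noise$threshold
  D[mask] <- 0
  structure(list(D = D, mask_below_threshold = mask, noise = noise,
                 mean_oct = mean_oct),
            class = "octa_volume")
}

#' Decorrelation angiography with OCT-signal thresholding
#'
#' Composes [decorrelate()], [estimate_noise()] and [apply_threshold()] and
#' carries preset and provenance forward.
#'
#' @param volume `oct_volume`.
#' @param noise_region optional logical voxel mask; default vitreous.
#' @return `octa_volume` with `preset`, `bm`, `ilm`, `axial_pitch` and
#'   `provenance` attached.
#' @export
run_angiography <- function(volume, noise_region = NULL) {
  D <- decorrelate(volume)
  noise <- estimate_noise(volume, noise_region)
  out <- apply_threshold(D, mean_oct(volume), noise)
  out$preset <- volume$preset
  out$bm <- volume$bm
  out$ilm <- volume$ilm
  out$axial_pitch <- volume$axial_pitch
  out$provenance <- volume$provenance
  out
}

#' @export
print.octa_volume <- function(x, ...) {
  d <- dim(x$D)
  cat("<octa_volume> grid ", d[1], "x", d[2], "x", d[3], ", ",
      sprintf("%.1f%% voxels below threshold %.4g\n",
              100 * mean(x$mask_below_threshold), x$noise$threshold), sep = "")
  invisible(x)
}
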