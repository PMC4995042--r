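#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (the convention used
#' for the printed study percentages), unlike [base::round()] which rounds
#' half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Binary erosion of a lateral mask
#'
#' Erodes a logical matrix with a 3x3 square structuring element, repeated
#' `px` times. Pixels outside the image count as background, so the image
#' border is eroded too.
#'
#' @param mask logical matrix.
#' @param px number of erosion passes (pixels removed from every boundary).
#' @return logical matrix of the same dimension.
#' @export
erode_mask <- function(mask, px = 1) {
  stopifnot(is.matrix(mask))
  m <- mask
  storage.mode(m) <- "logical"
  for (i in seq_len(px)) {
    nr <- nrow(m); nc <- ncol(m)
    padded <- matrix(FALSE, nr + 2, nc + 2)
    padded[2:(nr + 1), 2:(nc + 1)] <- m
    out <- m
    for (di in 0:2) for (dj in 0:2) {
      out <- out & padded[(1 + di):(nr + di), (1 + dj):(nc + dj)]
    }
    m <- out
  }
  m
}

# Envelope (amplitude) correlation of two unit-variance circular complex
# Gaussian fields whose complex field correlation has squared magnitude k2.
# Closed form via the Gauss hypergeometric series 2F1(-1/2, -1/2; 1; k2),
# which converges rapidly on [0, 1].
envelope_correlation <- function(k2) {
  stopifnot(all(k2 >= 0 & k2 <= 1))
  f <- rep(1, length(k2))
  term <- rep(1, length(k2))
  for (n in 1:40) {
    a <- (-0.5 + n - 1)
    term <- term * (a * a) / (n * n) * k2
    f <- f + term
  }
  (pi / 2 * (f - 1)) / (2 - pi / 2)
}

# Inverse of envelope_correlation: field mixing coefficient a such that the
# amplitude correlation of |g_n| across one repeat interval equals rho_amp.
field_coefficient <- function(rho_amp) {
  vapply(rho_amp, function(r) {
    if (r >= 1) return(1)
    if (r <= 0) return(0)
    k2 <- stats::uniroot(function(x) envelope_correlation(x) - r,
                         c(0, 1), tol = 1e-12)$root
    sqrt(k2)
  }, numeric(1))
}

# Lateral pixel-center coordinates (mm) of a phantom/device grid.
pixel_centers <- function(n, extent_mm) {
  (seq_len(n) - 0.5) * extent_mm / n
}
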