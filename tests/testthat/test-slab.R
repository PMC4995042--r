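test_that("slab spec validates its window", {
  s <- slab_spec()
  expect_equal(c(s$offset_lo, s$offset_hi), c(30, 60))
  expect_error(slab_spec(60, 30), "offset")
  expect_error(slab_spec(-1, 30), "offset")
})

test_that("slab index arithmetic takes exactly 10 samples at 3 um pitch", {
  # field value = 0-based axial index, flat BM at 300 um (index 100):
  # window [110, 120) -> mean of 110..119 = 114.5
  nz <- 200
  field <- array(rep(0:(nz - 1), each = 16), c(4, 4, nz))
  bm <- matrix(300, 4, 4)
  slab <- extract_slab(field, bm, slab_spec(30, 60), 3)
  expect_true(all(slab == 114.5))
})

test_that("a linear depth ramp projects to the window midpoint", {
  nz <- 200
  field <- array(rep((0:(nz - 1)) * 3, each = 16), c(4, 4, nz))  # depth in um
  bm <- matrix(300, 4, 4)
  slab <- extract_slab(field, bm, slab_spec(30, 60), 3)
  expect_true(all(abs(slab - (300 + 45)) <= 3))
})

test_that("slab extraction is linear and constant-preserving", {
  set.seed(3)
  f <- array(rnorm(4 * 4 * 200), c(4, 4, 200))
  g <- array(rnorm(4 * 4 * 200), c(4, 4, 200))
  bm <- matrix(c(300, 303, 306, 300), 4, 4)
  s <- slab_spec()
  lhs <- extract_slab(2 * f + 3 * g, bm, s, 3)
  rhs <- 2 * extract_slab(f, bm, s, 3) + 3 * extract_slab(g, bm, s, 3)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  cf <- array(7, c(4, 4, 200))
  expect_true(all(extract_slab(cf, bm, s, 3) == 7))
})

test_that("shifting BM and structure together leaves the slab unchanged", {
  set.seed(4)
  nz <- 200
  f <- array(rnorm(4 * 4 * nz), c(4, 4, nz))
  shift_px <- 10  # 30 um at 3 um pitch
  f_shifted <- array(0, c(4, 4, nz))
  f_shifted[, , (1 + shift_px):nz] <- f[, , 1:(nz - shift_px)]
  bm <- matrix(300, 4, 4)
  s1 <- extract_slab(f, bm, slab_spec(), 3)
  s2 <- extract_slab(f_shifted, bm + 30, slab_spec(), 3)
  expect_equal(s1, s2)
})

test_that("a slab leaving the volume names the offending pixel", {
  f <- array(1, c(4, 4, 50))
  bm <- matrix(60, 4, 4)
  bm[2, 3] <- 100  # window end round(100/3) + 20 > 50
  expect_error(extract_slab(f, bm, slab_spec(), 3), "\\(2, 3\\)")
})

test_that("ground-truth segmentation returns the phantom BM surface", {
  ph <- make_phantom(small_config(32))
  v <- simulate_volume(ph, device_preset("SD840"), seed = 1)
  bm <- segment_bm(v, "ground_truth", ph)
  expect_equal(bm, ph$bm)
  expect_error(segment_bm(v, "ground_truth"), "phantom")
})

test_that("estimated segmentation finds BM on a flat noiseless phantom", {
  cfg <- small_config(48)
  cfg$drusen <- list()
  ph <- make_phantom(cfg)
  v <- simulate_volume(ph, device_preset("SD840"), seed = 4,
                       noise_on = FALSE, speckle_on = FALSE)
  est <- segment_bm(v, "estimated", ph)
  expect_gte(mean(abs(est - ph$bm) <= v$axial_pitch), 0.99)
  expect_false(any(attr(est, "flagged")))
  # an all-noise volume has no RPE peak to segment
  cfg0 <- small_config(16)
  cfg0$optics$reflectivity <- rep(0, 6)
  ph0 <- make_phantom(cfg0)
  v0 <- simulate_volume(ph0, device_preset("SD840"), seed = 5)
  expect_error(segment_bm(v0, "estimated"), "no RPE peak")
})

test_that("estimated segmentation fails under drusen and is flagged", {
  ph <- make_phantom(small_config(64))
  v <- simulate_volume(ph, device_preset("SD840"), seed = 4,
                       noise_on = FALSE, speckle_on = FALSE)
  est <- segment_bm(v, "estimated", ph)
  flagged <- attr(est, "flagged")
  center <- which(ph$elevation == max(ph$elevation), arr.ind = TRUE)[1, ]
  expect_true(flagged[center[1], center[2]])
  # deviation at the druse apex is on the order of the druse height
  expect_lt(est[center[1], center[2]], ph$bm[center[1], center[2]] - 50)
})

test_that("en face pair obeys masking consistency", {
  set.seed(6)
  D <- array(runif(4 * 4 * 200), c(4, 4, 200))
  m <- array(1, c(4, 4, 200))
  m[1:2, , ] <- 0   # below any positive threshold
  ns <- structure(list(threshold = 0.5), class = "noise_stats")
  oc <- apply_threshold(D, m, ns)
  oc$preset <- device_preset("SD840")
  oc$axial_pitch <- 3
  pair <- make_enface_pair(oc, matrix(300, 4, 4), slab_spec())
  expect_true(all(pair$masked_fraction[1:2, ] == 1))
  expect_true(all(pair$octa_slab[1:2, ] == 0))
  expect_true(all(pair$masked_fraction[3:4, ] == 0))
  expect_true(all(pair$octa_slab >= 0 & pair$octa_slab <= 1))
})

test_that("uniform flow without attenuation gives a structure-free OCTA slab", {
  cfg <- disable_attenuation(small_config(64))
  cfg$drusen <- list()
  ph <- make_phantom(cfg)
  v <- simulate_volume(ph, device_preset("SD840", rolloff_6db_um = Inf), seed = 5)
  pair <- make_enface_pair(run_angiography(v))
  # oracle: Monte-Carlo CV of a mean of 10 voxelwise decorrelation values at
  # the same amplitude correlation, computed independently of the pipeline
  set.seed(99)
  nmc <- 2e4
  a <- 0.6256096  # field coefficient giving amplitude correlation e^-1
  d_mc <- replicate(10, {
    g1 <- complex(real = rnorm(nmc, 0, 1 / sqrt(2)),
                  imaginary = rnorm(nmc, 0, 1 / sqrt(2)))
    g2 <- a * g1 + sqrt(1 - a^2) * complex(real = rnorm(nmc, 0, 1 / sqrt(2)),
                                           imaginary = rnorm(nmc, 0, 1 / sqrt(2)))
    A1 <- Mod(g1); A2 <- Mod(g2)
    1 - A1 * A2 / (0.5 * (A1^2 + A2^2))
  })
  slab_mc <- rowMeans(d_mc)
  cv_oracle <- stats::sd(slab_mc) / mean(slab_mc)
  cv <- stats::sd(pair$octa_slab) / mean(pair$octa_slab)
  expect_lt(abs(cv - cv_oracle), 0.3 * cv_oracle)
  # and the slab mean matches the Monte-Carlo mean
  expect_lt(abs(mean(pair$octa_slab) - mean(slab_mc)), 0.05)
})

test_that("the OCT slab is darker under a druse on the SD device", {
  ph <- make_phantom(small_config(64))
  v <- simulate_volume(ph, device_preset("SD840"), seed = 7)
  pair <- make_enface_pair(run_angiography(v))
  roi <- druse_roi(ph, ph$drusen[1, ])
  away <- erode_mask(!Reduce(`|`, lapply(1:nrow(ph$drusen), function(i)
    druse_roi(ph, ph$drusen[i, ]))), 2)
  expect_lt(median(pair$oct_slab[roi]), median(pair$oct_slab[away]))
})
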