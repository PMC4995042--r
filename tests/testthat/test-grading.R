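fake_pair <- function(octa, oct, device = "SD840") {
  structure(list(oct_slab = oct, octa_slab = octa,
                 masked_fraction = 0 * octa, spec = slab_spec(),
                 device = device),
            class = "enface_pair")
}

test_that("reader parameters are validated", {
  r <- reader_params()
  expect_equal(c(r$k, r$f), c(0.5, 0.5))
  expect_error(reader_params(k = 1.2), "k must")
  expect_error(reader_params(f = 0), "f must")
})

test_that("assess_roi flags a masked ROI and not a background-like ROI", {
  octa <- matrix(0.2, 40, 40)
  oct <- matrix(0.5, 40, 40)
  roi <- matrix(FALSE, 40, 40); roi[18:22, 18:22] <- TRUE
  # ROI entirely zeroed by thresholding, background positive
  octa_masked <- octa; octa_masked[roi] <- 0
  a <- assess_roi(fake_pair(octa_masked, oct), roi)
  expect_true(a$low_octa)
  # ROI statistically identical to background
  b <- assess_roi(fake_pair(octa, oct), roi)
  expect_false(b$low_octa)
  expect_false(b$low_oct)
  expect_error(assess_roi(fake_pair(octa, oct), roi & FALSE), "empty ROI")
})

test_that("raising the low-pixel factor k never un-flags an ROI", {
  set.seed(10)
  roi <- matrix(FALSE, 40, 40); roi[10:20, 10:20] <- TRUE
  octa <- matrix(runif(1600, 0, 0.3), 40, 40)
  oct <- matrix(runif(1600, 0.3, 0.6), 40, 40)
  pair <- fake_pair(octa, oct)
  ks <- seq(0.05, 0.95, by = 0.05)
  flags <- vapply(ks, function(k) {
    assess_roi(pair, roi, reader_params(k = k))$low_octa
  }, logical(1))
  expect_true(all(diff(as.integer(flags)) >= 0))
})

test_that("druse classification follows the ambiguity definitions", {
  sd <- function(lo, lc) list(device = "SD840", low_octa = lo, low_oct = lc)
  ss <- function(lo, lc) list(device = "SS1050", low_octa = lo, low_oct = lc)
  # ambiguous SD loss + no SS loss = SD false positive
  g <- classify_druse(sd(TRUE, TRUE), ss(FALSE, FALSE))
  expect_equal(g$sd_class, "ambiguous")
  expect_true(g$sd_false_positive)
  expect_false(g$ss_false_positive)
  # unambiguous loss on both devices: no false positives
  g <- classify_druse(sd(TRUE, FALSE), ss(TRUE, FALSE))
  expect_equal(c(g$sd_class, g$ss_class), c("unambiguous", "unambiguous"))
  expect_false(g$sd_false_positive || g$ss_false_positive)
  # no loss anywhere
  g <- classify_druse(sd(FALSE, FALSE), ss(FALSE, FALSE))
  expect_equal(c(g$sd_class, g$ss_class), c("none", "none"))
  expect_false(any(c(g$sd_loss, g$ss_loss, g$sd_false_positive, g$ss_false_positive)))
  expect_error(classify_druse(ss(TRUE, TRUE), sd(TRUE, TRUE)), "device mismatch")
})

test_that("classification matches a brute-force truth table on all 64 cases", {
  tf <- c(TRUE, FALSE)
  cases <- expand.grid(sd_lo = tf, sd_lc = tf, ss_lo = tf, ss_lc = tf,
                       KEEP.OUT.ATTRS = FALSE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    g <- classify_druse(
      list(device = "SD840", low_octa = cs$sd_lo, low_oct = cs$sd_lc),
      list(device = "SS1050", low_octa = cs$ss_lo, low_oct = cs$ss_lc))
    # independent re-derivation straight from the definitions
    sd_class <- if (!cs$sd_lo) "none" else if (cs$sd_lc) "ambiguous" else "unambiguous"
    ss_class <- if (!cs$ss_lo) "none" else if (cs$ss_lc) "ambiguous" else "unambiguous"
    expect_identical(g$sd_class, sd_class)
    expect_identical(g$ss_class, ss_class)
    expect_identical(g$sd_loss, (g$sd_class != "none"))
    expect_identical(g$ss_loss, (g$ss_class != "none"))
    expect_identical(g$sd_false_positive, sd_class == "ambiguous" && !cs$ss_lo)
    expect_identical(g$ss_false_positive, ss_class == "ambiguous" && !cs$sd_lo)
    # false positives impossible when the other device shows loss
    if (cs$ss_lo) expect_false(g$sd_false_positive)
    if (cs$sd_lo) expect_false(g$ss_false_positive)
  }
})

random_grades <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    classify_druse(
      list(device = "SD840", low_octa = runif(1) < 0.5, low_oct = runif(1) < 0.5),
      list(device = "SS1050", low_octa = runif(1) < 0.5, low_oct = runif(1) < 0.5))
  })
}

test_that("aggregation equals a brute-force recount and conserves classes", {
  for (s in 1:25) {
    n <- sample(1:40, 1)
    grades <- random_grades(n, s)
    agg <- aggregate_grades(grades)
    sd_classes <- vapply(grades, `[[`, character(1), "sd_class")
    ss_classes <- vapply(grades, `[[`, character(1), "ss_class")
    expect_equal(agg$sd$n_loss, sum(sd_classes != "none"))
    expect_equal(agg$sd$n_ambiguous, sum(sd_classes == "ambiguous"))
    expect_equal(agg$sd$n_unambiguous, sum(sd_classes == "unambiguous"))
    expect_equal(agg$sd$n_false_positive,
                 sum(vapply(grades, `[[`, logical(1), "sd_false_positive")))
    expect_equal(agg$ss$n_loss, sum(ss_classes != "none"))
    # conservation: ambiguous + unambiguous = losses, per device
    expect_equal(agg$sd$n_ambiguous + agg$sd$n_unambiguous, agg$sd$n_loss)
    expect_equal(agg$ss$n_ambiguous + agg$ss$n_unambiguous, agg$ss$n_loss)
    if (agg$sd$n_loss > 0) {
      expect_equal(agg$sd$pct_ambiguous,
                   round_half_up(100 * agg$sd$n_ambiguous / agg$sd$n_loss, 1))
    }
  }
})

test_that("an empty cohort reports zero counts and absent percentages", {
  agg <- aggregate_grades(list())
  expect_equal(agg$n_drusen, 0)
  expect_equal(agg$sd$n_loss, 0)
  expect_true(is.na(agg$sd$pct_loss))
  expect_equal(render_summary_text(agg), "Zero drusen analyzed.")
})

test_that("percent agreement and kappa follow their definitions", {
  x <- c(rep("loss", 20), rep("none", 26))
  expect_equal(agreement(x, x), list(percent_agreement = 100, kappa = 1))
  # 45 matches of 46
  y <- x; y[1] <- "none"
  pa <- agreement(x, y)$percent_agreement
  expect_equal(round_half_up(pa, 1), 97.8)
  expect_error(agreement(x, y[-1]), "length")
  # independent random labels: kappa near zero
  set.seed(13)
  a <- sample(c("A", "B"), 1e4, replace = TRUE)
  b <- sample(c("A", "B"), 1e4, replace = TRUE)
  expect_lt(abs(agreement(a, b)$kappa), 0.05)
})

test_that("the synthetic 23-druse table reproduces every printed tally", {
  fx <- grading_fixture()
  expect_equal(nrow(fx), 23)
  res <- classify_table(fx)
  s <- res$summary
  expect_equal(s$sd$n_loss, 17);  expect_equal(s$sd$pct_loss, 73.9)
  expect_equal(s$sd$n_ambiguous, 14);  expect_equal(s$sd$pct_ambiguous, 82.4)
  expect_equal(s$sd$n_unambiguous, 3); expect_equal(s$sd$pct_unambiguous, 17.6)
  expect_equal(s$sd$n_false_positive, 10)
  expect_equal(s$sd$pct_false_positive, 58.8)
  expect_equal(s$ss$n_loss, 7);   expect_equal(s$ss$pct_loss, 30.4)
  expect_equal(s$ss$n_unambiguous, 7)
  expect_equal(s$ss$n_false_positive, 0)
  # consistency: any assignment is accepted as long as the tallies hold;
  # this block asserts the tallies, not the row order
  txt <- render_summary_text(s)
  expect_true(any(grepl("SD840: 17/23 (73.9%)", txt, fixed = TRUE)))
})

test_that("grade_cohort composes assessment, classification and aggregation", {
  # two synthetic drusen: one masked on SD only, one clean
  n <- 60
  octa_sd <- matrix(0.2, n, n); oct_sd <- matrix(0.5, n, n)
  octa_ss <- matrix(0.2, n, n); oct_ss <- matrix(0.5, n, n)
  roi1 <- matrix(FALSE, n, n); roi1[10:20, 10:20] <- TRUE
  roi2 <- matrix(FALSE, n, n); roi2[35:45, 35:45] <- TRUE
  octa_sd[roi1] <- 0; oct_sd[roi1] <- 0.1   # ambiguous loss on SD
  pairs <- list(SD840 = fake_pair(octa_sd, oct_sd, "SD840"),
                SS1050 = fake_pair(octa_ss, oct_ss, "SS1050"))
  out <- grade_cohort(pairs, list(roi1, roi2))
  expect_equal(nrow(out$grades), 2)
  expect_equal(out$grades$sd_class, c("ambiguous", "none"))
  expect_true(out$grades$sd_false_positive[1])
  expect_equal(out$summary$sd$n_false_positive, 1)
  expect_equal(out$summary$ss$n_loss, 0)
})
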