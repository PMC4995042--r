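#' Parameterized automatic reader
#'
#' Replaces the human readers' qualitative "low signal" judgment with two
#' explicit parameters: a slab pixel is *low* when its value falls below
#' `k` times the median of the background region, and an ROI is graded as
#' low-signal when at least a fraction `f` of its pixels are low. The
#' background is the slab outside every druse footprint, eroded by 2 pixels.
#'
#' @param k low-pixel factor, 0 < k < 1.
#' @param f low-area fraction, 0 < f <= 1.
#' @return object of class `reader_params`.
#' @export
reader_params <- function(k = 0.5, f = 0.5) {
  if (!(k > 0 && k < 1)) stop("k must lie in (0, 1)")
  if (!(f > 0 && f <= 1)) stop("f must lie in (0, 1]")
  structure(list(k = k, f = f), class = "reader_params")
}

#' Assess one druse ROI on an en face pair
#'
#' Records whether the OCTA slab shows low signal under the druse, and
#' whether the OCT slab does in the corresponding area (consulted when OCTA
#' signal is low, mirroring the grading workflow). Deterministic given the
#' images and reader parameters.
#'
#' @param pair `enface_pair`.
#' @param roi logical lateral mask of the druse footprint.
#' @param reader `reader_params`.
#' @param background logical lateral mask of the reference region; defaults
#'   to the complement of `roi` eroded by 2 pixels. When grading a cohort
#'   use the complement of *all* druse ROIs (see [grade_cohort()]).
#' @return list with `device`, `low_octa`, `low_oct`.
#' @export
assess_roi <- function(pair, roi, reader = reader_params(),
                       background = NULL) {
  if (!any(roi)) stop("empty ROI")
  if (is.null(background)) background <- erode_mask(!roi, 2)
  if (!any(background)) stop("empty background region")
  low_frac <- function(img) {
    ref <- reader$k * stats::median(img[background])
    mean(img[roi] < ref)
  }
  list(device = pair$device,
       low_octa = low_frac(pair$octa_slab) >= reader$f,
       low_oct = low_frac(pair$oct_slab) >= reader$f)
}

#' Classify a druse from its two device assessments
#'
#' Per device: *loss* means low OCTA signal; a loss is *ambiguous* when the
#' corresponding OCT signal is also low (so masking cannot be excluded) and
#' *unambiguous* when OCT signal is preserved (interpretable as a true flow
#' alteration). *False-positive flow impairment* on one device is an
#' ambiguous loss on that device with no OCTA signal loss on the other —
#' a thresholding/shadowing artifact rather than choriocapillaris pathology.
#'
#' @param sd assessment from the SD840 device (see [assess_roi()]).
#' @param ss assessment from the SS1050 device.
#' @return list of class `druse_grade` with `sd_loss`, `sd_class`,
#'   `ss_loss`, `ss_class`, `sd_false_positive`, `ss_false_positive`.
#' @export
classify_druse <- function(sd, ss) {
  if (!identical(sd$device, "SD840") || !identical(ss$device, "SS1050")) {
    stop("device mismatch: expected assessments from SD840 and SS1050")
  }
  cls <- function(a) {
    if (!a$low_octa) "none" else if (a$low_oct) "ambiguous" else "unambiguous"
  }
  sd_class <- cls(sd); ss_class <- cls(ss)
  structure(list(
    sd_loss = sd$low_octa, sd_class = sd_class,
    ss_loss = ss$low_octa, ss_class = ss_class,
    sd_false_positive = sd_class == "ambiguous" && !ss$low_octa,
    ss_false_positive = ss_class == "ambiguous" && !sd$low_octa
  ), class = "druse_grade")
}

#' Aggregate per-druse grades into study-level tallies
#'
#' Counts losses, ambiguous/unambiguous classes and false positives per
#' device. Percentages use the printed convention: loss percentage over all
#' drusen; ambiguous, unambiguous and false-positive percentages over that
#' device's losses; all rounded half-up to one decimal. An empty cohort
#' yields zero counts with percentages reported as `NA`.
#'
#' @param grades list of `druse_grade` objects.
#' @return object of class `cohort_summary`: `n_drusen` plus `sd` and `ss`
#'   sublists with `n_loss`, `pct_loss`, `n_ambiguous`, `pct_ambiguous`,
#'   `n_unambiguous`, `pct_unambiguous`, `n_false_positive`,
#'   `pct_false_positive`.
#' @export
aggregate_grades <- function(grades) {
  n <- length(grades)
  one <- function(prefix) {
    loss <- sum(vapply(grades, `[[`, logical(1), paste0(prefix, "_loss")))
    classes <- vapply(grades, `[[`, character(1), paste0(prefix, "_class"))
    fp <- sum(vapply(grades, `[[`, logical(1), paste0(prefix, "_false_positive")))
    amb <- sum(classes == "ambiguous")
    unamb <- sum(classes == "unambiguous")
    pct <- function(num, den) {
      if (den == 0) NA_real_ else round_half_up(100 * num / den, 1)
    }
    list(n_loss = loss, pct_loss = pct(loss, n),
         n_ambiguous = amb, pct_ambiguous = pct(amb, loss),
         n_unambiguous = unamb, pct_unambiguous = pct(unamb, loss),
         n_false_positive = fp, pct_false_positive = pct(fp, loss))
  }
  structure(list(n_drusen = n, sd = one("sd"), ss = one("ss")),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(render_summary_text(x), sep = "\n")
  invisible(x)
}

#' Percent agreement and Cohen's kappa between two label lists
#'
#' `percent_agreement = 100 * matches / n`; kappa uses chance agreement from
#' the product of the two readers' marginal label frequencies. Perfect
#' observed agreement yields kappa = 1 regardless of the marginals.
#'
#' @param grades_a,grades_b equal-length vectors of labels.
#' @return list with `percent_agreement` and `kappa`.
#' @export
agreement <- function(grades_a, grades_b) {
  if (length(grades_a) != length(grades_b)) stop("label lists differ in length")
  n <- length(grades_a)
  if (n < 1) stop("need at least one pair of labels")
  a <- as.character(grades_a); b <- as.character(grades_b)
  po <- mean(a == b)
  labs <- union(a, b)
  pe <- sum(vapply(labs, function(l) mean(a == l) * mean(b == l), numeric(1)))
  kappa <- if (po == 1) 1 else (po - pe) / (1 - pe)
  list(percent_agreement = 100 * po, kappa = kappa)
}

#' Grade a cohort of drusen on both devices
#'
#' Maps [assess_roi()] over devices and druse ROIs using a shared background
#' (all slab pixels outside every ROI, eroded by 2 pixels), classifies each
#' druse with [classify_druse()] and aggregates.
#'
#' @param pairs_by_device named list with elements `SD840` and `SS1050`,
#'   each an `enface_pair`.
#' @param rois list of logical lateral masks, one per druse.
#' @param reader `reader_params`.
#' @return list with `grades` (data.frame, one row per druse), `grade_list`
#'   (the `druse_grade` objects) and `summary` (`cohort_summary`).
#' @export
grade_cohort <- function(pairs_by_device, rois, reader = reader_params()) {
  stopifnot(all(c("SD840", "SS1050") %in% names(pairs_by_device)))
  union_roi <- Reduce(`|`, rois)
  background <- erode_mask(!union_roi, 2)
  if (!any(background)) stop("empty background region")
  grade_list <- vector("list", length(rois))
  rows <- vector("list", length(rois))
  for (i in seq_along(rois)) {
    sd <- assess_roi(pairs_by_device$SD840, rois[[i]], reader, background)
    ss <- assess_roi(pairs_by_device$SS1050, rois[[i]], reader, background)
    gr <- classify_druse(sd, ss)
    grade_list[[i]] <- gr
    rows[[i]] <- data.frame(
      druse_id = i,
      sd_low_octa = sd$low_octa, sd_low_oct = sd$low_oct,
      ss_low_octa = ss$low_octa, ss_low_oct = ss$low_oct,
      sd_class = gr$sd_class, ss_class = gr$ss_class,
      sd_false_positive = gr$sd_false_positive,
      ss_false_positive = gr$ss_false_positive,
      stringsAsFactors = FALSE
    )
  }
  list(grades = do.call(rbind, rows), grade_list = grade_list,
       summary = aggregate_grades(grade_list))
}

#' Run the full simulation-to-grading study on one phantom
#'
#' End-to-end pipeline: simulate both device presets from the phantom
#' configuration, compute thresholded decorrelation angiography, project
#' 30-60 um sub-BM en face slabs, and grade every analysis-eligible druse.
#' The two device simulations use seeds derived from the root seed.
#'
#' @param config phantom configuration (see [default_phantom_config()]).
#' @param reader `reader_params`.
#' @param seed root integer seed.
#' @param spec `slab_spec`.
#' @param bm_mode `"ground_truth"` (default) or `"estimated"`.
#' @return list with `phantom`, `pairs` (per device), `noise` (per device),
#'   `grades`, `grade_list`, `summary`.
#' @export
run_study <- function(config = default_phantom_config(),
                      reader = reader_params(), seed = 1L,
                      spec = slab_spec(), bm_mode = "ground_truth") {
  phantom <- make_phantom(config, seed)
  pairs <- list()
  noise <- list()
  for (dev in c("SD840", "SS1050")) {
    preset <- device_preset(dev)
    dev_seed <- (as.integer(seed) * 7L + match(dev, c("SD840", "SS1050"))) %% .Machine$integer.max
    vol <- simulate_volume(phantom, preset, seed = dev_seed)
    octa <- run_angiography(vol)
    bm <- segment_bm(vol, bm_mode, phantom)
    pairs[[dev]] <- make_enface_pair(octa, bm, spec)
    noise[[dev]] <- octa$noise
  }
  eligible <- eligible_drusen(phantom)
  rois <- lapply(seq_len(nrow(eligible)), function(i) {
    druse_roi(phantom, eligible[i, ])
  })
  graded <- grade_cohort(pairs, rois, reader)
  c(list(phantom = phantom, pairs = pairs, noise = noise), graded)
}
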