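#' Load the synthetic 23-druse grading table
#'
#' The study cohort comprised 23 large soft drusen graded on both devices,
#' but only the aggregate tallies were published. This fixture is one
#' per-druse assignment, constructed (and labelled synthetic) to satisfy
#' every printed tally simultaneously: drusen 1-10 show ambiguous loss on
#' SD840 with no SS1050 loss (the SD false positives), 11-14 ambiguous on
#' SD840 with unambiguous SS1050 loss, 15-17 unambiguous on both, and 18-23
#' no loss on either device. Any other assignment matching all tallies is
#' equally valid; [aggregate_grades()] does not depend on the ordering.
#'
#' @param path CSV path; defaults to the copy shipped with the package.
#' @return data.frame with columns `druse_id`, `sd_low_octa`, `sd_low_oct`,
#'   `ss_low_octa`, `ss_low_oct`.
#' @export
grading_fixture <- function(path = system.file("extdata",
                                               "drusen_cohort23_synthetic.csv",
                                               package = "ccocta")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("druse_id", "sd_low_octa", "sd_low_oct", "ss_low_octa", "ss_low_oct")
  if (!all(needed %in% names(df))) {
    stop("grading table must have columns: ", paste(needed, collapse = ", "))
  }
  df
}

#' Classify and aggregate a per-druse assessment table
#'
#' Runs [classify_druse()] on every row of a grading table (as returned by
#' [grading_fixture()]) and aggregates the cohort.
#'
#' @param table data.frame in the [grading_fixture()] format.
#' @return list with `grade_list` and `summary` (`cohort_summary`).
#' @export
classify_table <- function(table) {
  grade_list <- lapply(seq_len(nrow(table)), function(i) {
    classify_druse(
      list(device = "SD840", low_octa = table$sd_low_octa[i],
           low_oct = table$sd_low_oct[i]),
      list(device = "SS1050", low_octa = table$ss_low_octa[i],
           low_oct = table$ss_low_oct[i])
    )
  })
  list(grade_list = grade_list, summary = aggregate_grades(grade_list))
}
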