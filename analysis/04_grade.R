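#!/usr/bin/env Rscript
# Stage 4 — per-druse grading and cohort tallies on the simulated eye.
#
# Grades every analysis-eligible druse (diameter >= 165 um) on both en face
# pairs with the default automatic reader (k = 0.5, f = 0.5), classifies
# each as none / ambiguous / unambiguous with cross-device false-positive
# flags, aggregates the cohort, and compares two reader parameterizations
# for interreader agreement. CSVs go to results/.

suppressMessages(library(ccocta))

phantom <- make_phantom(default_phantom_config(), 1L)
pairs <- list()
for (dev in c("SD840", "SS1050")) {
  sidecar <- file.path("scratch", "enface", paste0(tolower(dev), ".json"))
  if (!file.exists(sidecar)) {
    stop("missing stage-3 output ", sidecar, "; run analysis/03_slabs.R first")
  }
  pairs[[dev]] <- read_enface_pair(sidecar)
}

eligible <- eligible_drusen(phantom)
rois <- lapply(seq_len(nrow(eligible)), function(i) druse_roi(phantom, eligible[i, ]))
cat(nrow(eligible), "eligible drusen of", nrow(phantom$drusen), "total\n")

graded <- grade_cohort(pairs, rois, reader_params())
cat(render_summary_text(graded$summary), sep = "\n")
write_grades(graded, "results", "simulated_cohort")

# a second, slightly stricter reader for interreader agreement
graded_b <- grade_cohort(pairs, rois, reader_params(k = 0.45, f = 0.5))
agr <- agreement(c(graded$grades$sd_low_octa, graded$grades$ss_low_octa),
                 c(graded_b$grades$sd_low_octa, graded_b$grades$ss_low_octa))
cat(sprintf("Interreader agreement (k = 0.50 vs 0.45): %.1f%%, kappa = %.3f\n",
            agr$percent_agreement, agr$kappa))
write.csv(data.frame(percent_agreement = agr$percent_agreement,
                     kappa = agr$kappa),
          file.path("results", "interreader_agreement.csv"), row.names = FALSE)
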