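#!/usr/bin/env Rscript
# Stage 3 — Bruch's-membrane-referenced en face choriocapillaris slabs.
#
# Flattens each OCTA volume to the ground-truth BM and mean-projects the
# OCT amplitude, the thresholded decorrelation and the below-threshold mask
# over the 30-60 um window beneath BM. Writes the en face pairs to
# scratch/enface and per-device slab statistics to results/slab_stats.csv.

suppressMessages(library(ccocta))

phantom <- make_phantom(default_phantom_config(), 1L)
rows <- list()
for (dev in c("SD840", "SS1050")) {
  sidecar <- file.path("scratch", "octa", paste0(tolower(dev), ".json"))
  if (!file.exists(sidecar)) {
    stop("missing stage-2 output ", sidecar, "; run analysis/02_angiography.R first")
  }
  octa <- read_octa_volume(sidecar)
  pair <- make_enface_pair(octa, phantom$bm, slab_spec())
  print(pair)
  write_enface_pair(pair, file.path("scratch", "enface"), tolower(dev))
  rows[[dev]] <- data.frame(
    device = dev,
    oct_slab_median = median(pair$oct_slab),
    octa_slab_median = median(pair$octa_slab),
    masked_fraction_mean = mean(pair$masked_fraction)
  )
}
dir.create("results", showWarnings = FALSE)
stats <- do.call(rbind, rows)
write.csv(stats, file.path("results", "slab_stats.csv"), row.names = FALSE)
print(stats)
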