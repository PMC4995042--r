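#!/usr/bin/env Rscript
# Stage 2 — decorrelation angiography with OCT-signal thresholding.
#
# Reads the stage-1 volumes, computes the pairwise amplitude decorrelation,
# estimates the noise from the vitreous and zeroes every voxel whose mean
# OCT amplitude falls below mean + 2 sd of the noise. Reports how much of
# each volume is masked — the quantity at the heart of the ambiguity
# problem — and writes the OCTA volumes to scratch/octa.

suppressMessages(library(ccocta))

for (dev in c("SD840", "SS1050")) {
  sidecar <- file.path("scratch", "volumes", paste0(tolower(dev), ".json"))
  if (!file.exists(sidecar)) {
    stop("missing stage-1 output ", sidecar, "; run analysis/01_simulate.R first")
  }
  vol <- read_oct_volume(sidecar)
  octa <- run_angiography(vol)
  print(octa$noise)
  cat(sprintf("%s: %.1f%% of voxels below threshold\n", dev,
              100 * mean(octa$mask_below_threshold)))
  write_octa_volume(octa, file.path("scratch", "octa"), tolower(dev))
}
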