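#!/usr/bin/env Rscript
# Ploidy and binucleation analysis: generate an untreated and a "treated"
# cardiomyocyte nucleus population (the treated one with a higher tetraploid
# fraction and more Ki-67+ cycling nuclei), gate to marker-positive
# Ki-67-negative nuclei, derive 2N/4N/8N thresholds from the DNA-content
# histogram, and quantify class fractions and nuclei per cell.
#
# Finding (seed 1): histogram-valley thresholds recover the generating class
# fractions within ~1 point, and the treated population shows the configured
# tetraploid shift (~27% -> ~39%) with unchanged binucleation.

library(fuccicycle)

out <- "results/ploidy"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

conditions <- list(
  untreated = ploidy_population_spec(c(0.70, 0.27, 0.03),
                                     frac_ki67_pos = 0.11),
  treated = ploidy_population_spec(c(0.58, 0.39, 0.03),
                                   frac_ki67_pos = 0.23))

summary_rows <- list()
for (cond in names(conditions)) {
  pop <- generate_ploidy_population(conditions[[cond]],
                                    seed = derive_seed(1L, cond))
  gated <- gate_nuclei(pop)
  thr <- derive_ploidy_thresholds(gated$dna_intensity)
  pr <- call_ploidy(gated, thr)
  bn <- binucleation_fraction(pop)
  ki67 <- marker_positive_fraction(pop, "ki67")
  cat(sprintf("\n== %s ==\n", cond))
  cat(sprintf("gated nuclei: %d; thresholds: %.3f / %.3f (2N mode %.3f)\n",
              pr$n_gated, thr$boundaries[1], thr$boundaries[2],
              thr$reference_2n_mode))
  cat(sprintf("ploidy fractions (2N/4N/8N+): %s\n",
              paste(sprintf("%.1f%%", 100 * pr$fractions), collapse = " / ")))
  cat(sprintf("Ki-67+: %.1f%%; binucleated cells: %.1f%%\n",
              ki67, 100 * bn$fractions[["bi"]]))
  summary_rows[[cond]] <- data.frame(
    condition = cond, n_gated = pr$n_gated,
    frac_2n = pr$fractions[1], frac_4n = pr$fractions[2],
    frac_8n = pr$fractions[3], ki67_pct = ki67,
    binucleated_frac = bn$fractions[["bi"]])
}
write.csv(do.call(rbind, summary_rows), file.path(out, "ploidy_summary.csv"),
          row.names = FALSE)
cat("\nOutputs written to", out, "\n")
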