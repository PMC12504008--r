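#!/usr/bin/env Rscript
# Step 2: harmonize the raw cohorts.
#
# Applies the variable-construction rules (ISCED collapse to the
# 3-category education score, registry onset-age delay removal, age cap at
# 90 and centering at 60, LDI-cutoff dementia calls) and writes the
# harmonized tables plus a sample-accounting report mirroring a
# participant flowchart.

library(cotwin)

in_dir <- "results/cohorts"
out_dir <- "results/harmonized"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ldi_cutoff <- cohort_config()$ldi_cutoff
for (f in list.files(in_dir, pattern = "\\.csv$")) {
  coh <- read_cohort(file.path(in_dir, f))
  h <- harmonize_cohort(coh, ldi_cutoff = ldi_cutoff)
  write_cohort(h, file.path(out_dir, f))
  cat("\n==", sub("\\.csv$", "", f), "==\n")
  print(accounting(h))
}
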