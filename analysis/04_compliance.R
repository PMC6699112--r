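#!/usr/bin/env Rscript
# Step 4: guideline evaluation and decision-tree classification.
#
# Scores every included product against its applicable guidelines (storage
# temperature window; one hour outside validated cooling; 24-hour transfusion
# deadline after a breach; 24-hour return deadline) and rolls the verdicts up
# into the four decision-tree categories.

library(coldtrace)

facility <- default_facility()
thresholds <- guideline_thresholds()
events <- read_events("results/events.csv", facility)
res <- assess_cohort(events, facility, thresholds)
records <- res$records

write_results(records, "results/compliance.jsonl")

tab <- category_table(records)
message(sprintf("classified %d products:", nrow(records)))
for (i in seq_len(nrow(tab))) {
  message(sprintf("  %-26s %3d (%.1f%%)", tab$category[i], tab$n[i], tab$pct[i]))
}
for (g in 1:4) {
  ok <- records[[sprintf("g%d_compliant", g)]]
  n_ok <- sum(ok, na.rm = TRUE)
  n_assessed <- sum(!is.na(ok))
  message(sprintf("  guideline %d: %d/%d compliant", g, n_ok, n_assessed))
}
message("wrote results/compliance.jsonl")
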