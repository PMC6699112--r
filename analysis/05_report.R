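#!/usr/bin/env Rscript
# Step 5: summary tables and distribution exports.
#
# Produces the category table, per-group mean/min/max summaries of the
# guideline evidence (temperatures and time intervals), and histogram CSVs of
# their distributions, per disposition group.

library(coldtrace)
suppressMessages(library(dplyr))

records <- read_results("results/compliance.jsonl")

tab <- category_table(records)
write.csv(tab, "results/category_table.csv", row.names = FALSE)

summaries <- bind_rows(
  records %>% filter(!is.na(g1_min_c)) %>% group_by(disposition) %>%
    reframe(summarize_group(g1_min_c)) %>% mutate(quantity = "min_temp_c"),
  records %>% filter(!is.na(g1_max_c)) %>% group_by(disposition) %>%
    reframe(summarize_group(g1_max_c)) %>% mutate(quantity = "max_temp_c"),
  records %>% filter(!is.na(g2_hours_outside_cooling)) %>% group_by(disposition) %>%
    reframe(summarize_group(g2_hours_outside_cooling)) %>%
    mutate(quantity = "hours_outside_cooling"),
  records %>% filter(!is.na(g4_hours_to_return)) %>% group_by(disposition) %>%
    reframe(summarize_group(g4_hours_to_return)) %>%
    mutate(quantity = "hours_to_return")
)
write.csv(summaries, "results/group_summaries.csv", row.names = FALSE)
export_distributions(records, "results")

message("category table:")
for (i in seq_len(nrow(tab))) {
  message(sprintf("  %-26s %3d (%.1f%%)", tab$category[i], tab$n[i], tab$pct[i]))
}
message("group summaries:")
for (i in seq_len(nrow(summaries))) {
  message(sprintf("  %-22s %-10s n=%3d mean=%6.2f range %.2f-%.2f",
                  summaries$quantity[i], summaries$disposition[i],
                  summaries$n[i], summaries$mean[i], summaries$min[i],
                  summaries$max[i]))
}
message("wrote results/category_table.csv, results/group_summaries.csv, results/hist_*.csv")
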