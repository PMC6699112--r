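#!/usr/bin/env Rscript
# Step 3: dataset selection and assessability.
#
# Applies the inclusion rules (never-left, lost, unseparable, no usable
# sub-dataset, in that precedence order) and reports, per included product,
# which guidelines can actually be evaluated on its data.

library(coldtrace)

facility <- default_facility()
thresholds <- guideline_thresholds()
events <- read_events("results/events.csv", facility)
res <- assess_cohort(events, facility, thresholds)

write.csv(res$inclusion, "results/inclusion.csv", row.names = FALSE)
write.csv(res$assessability, "results/assessability.csv", row.names = FALSE)

tab <- table(res$inclusion$exclusion_reason)
message(sprintf("included %d of %d products", sum(res$inclusion$included),
                nrow(res$inclusion)))
message("exclusions: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
by_g <- stats::aggregate(assessable ~ guideline_id,
                         data = res$assessability[res$assessability$applicable, ],
                         FUN = function(x) sprintf("%d/%d", sum(x), length(x)))
message("assessable (per applicable guideline): ",
        paste(sprintf("G%d %s", by_g$guideline_id, by_g$assessable),
              collapse = ", "))
message("wrote results/inclusion.csv and results/assessability.csv")
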