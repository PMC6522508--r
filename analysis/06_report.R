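#!/usr/bin/env Rscript
# Stage 6: assemble the Markdown report from the fitted artifacts.

library(konosmeld)

cohort <- read_registry("results/cohort_large.csv")
reg <- add_meld(cohort)
out <- derive_outcome(reg)

nh <- which(!reg$hcc)[seq_len(5000)]
tree <- fit_tree(reg$meld[nh], out$time_days[nh], out$event[nh],
                 tree_config())
tab <- find_exception_points(cohort)

write_report(cohort, tree = tree, exception_table = tab,
             path = "results/report.md")
cat("Wrote results/report.md\n")
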