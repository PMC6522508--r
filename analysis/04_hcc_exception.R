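#!/usr/bin/env Rscript
# Stage 4: MELD exception points for HCC candidates.
#
# HCC candidates often retain liver function, so their laboratory MELD
# understates waitlist risk. Above MELD 20 the presence of HCC does not
# affect waitlist survival; below it, each HCC band is matched to the
# non-HCC band with statistically indistinguishable survival, and the offset
# between the bands is the number of exception points.

library(konosmeld)
library(jsonlite)

cohort <- read_registry("results/cohort_large.csv")

# above the ceiling: HCC does not change waitlist survival
high <- compare_bands(cohort, c(21, 40), c(21, 40), horizon_days = 90)
print(high)

tab <- find_exception_points(cohort, hcc_bands = list(c(6L, 13L),
                                                      c(14L, 20L)),
                             offsets = 0:10, alpha = 0.05,
                             horizon_days = 90)
print(tab)
write.csv(as.data.frame(tab), "results/exception_table.csv",
          row.names = FALSE)
write_json(list(ceiling = attr(tab, "ceiling"),
                bands = as.data.frame(tab)),
           "results/exception_table.json", auto_unbox = TRUE, digits = 6)

cmp <- lapply(seq_len(nrow(tab)), function(i) {
  b <- c(tab$meld_lo[i], tab$meld_hi[i])
  compare_bands(cohort, b, pmin(b + tab$added_points[i], 40L))
})
invisible(lapply(cmp, print))

cat(sprintf("\nSelected offsets: [6,13] -> +%d, [14,20] -> +%d (p = %.2f, %.2f)\n",
            tab$added_points[1], tab$added_points[2],
            tab$p_value[1], tab$p_value[2]))
cat("Wrote results/exception_table.csv and exception_table.json\n")
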