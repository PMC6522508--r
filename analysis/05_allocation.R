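#!/usr/bin/env Rscript
# Stage 5: queue rankings under the staged broader-sharing model vs the
# previous CTP-status system.
#
# For an example donor offer, the same waitlist is ranked under both
# systems. The comparison shows the two headline behaviours of the reform:
# MELD 38-40 candidates reach the national tier regardless of region, and
# high-MELD status 2B candidates overtake low-MELD status 2A candidates.

library(konosmeld)

cohort <- read_registry("results/cohort.csv")
offer <- donor_offer(donor_region = 1, blood_type = "A")

meld_q <- rank_waitlist(cohort, offer, system = "meld")
old_q <- rank_waitlist(cohort, offer, system = "ctp_status")

keep <- c("queue_position", "id", "status", "allocation_meld", "meld",
          "hcc", "region", "follow_up_days", "tier_rank", "tier_label")
write.csv(meld_q[keep], "results/queue_meld.csv", row.names = FALSE)
write.csv(old_q[setdiff(keep, "tier_label")], "results/queue_ctp_status.csv",
          row.names = FALSE)

cat("Top 10 under the MELD staged model:\n")
print(head(meld_q[keep], 10), row.names = FALSE)
cat("\nTop 10 under the previous CTP-status system:\n")
print(head(old_q[setdiff(keep, "tier_label")], 10), row.names = FALSE)

# how far do the two systems disagree? rank displacement of shared top-50
top_old <- head(old_q$id, 50)
disp <- match(top_old, meld_q$id) - seq_along(top_old)
cat(sprintf("\nMedian displacement of the old system's top 50 under MELD: %+.0f positions\n",
            median(disp)))
cat("Wrote results/queue_meld.csv and queue_ctp_status.csv\n")
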