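test_that("tier assignment follows the staged broader-sharing rows", {
  # status 1 shares one combined tier regardless of region
  expect_equal(assign_tier("1", 12, 2, 1)$rank, 1L)
  # MELD 38-40 is the national broader-sharing tier even across regions
  expect_equal(assign_tier("2B", 39, 3, 1)$rank, 2L)
  # a national 31-37 candidate outranks a regional 21-30 candidate
  expect_equal(assign_tier("2B", 35, 2, 1)$rank, 4L)
  expect_equal(assign_tier("2B", 28, 1, 1)$rank, 5L)
  # regional vs national legs of the lower bands
  expect_equal(assign_tier("3", 15, 1, 1)$rank, 7L)
  expect_equal(assign_tier("3", 15, 2, 1)$rank, 8L)
  expect_error(assign_tier("2B", 20, 5, 1), "region")
  expect_error(assign_tier("2B", 45, 1, 1), "6, 40")
})

test_that("ABO filter keeps identical-or-compatible recipients", {
  expect_true(all(blood_compatible("O", c("A", "B", "AB", "O"))))
  expect_equal(blood_compatible("A", c("A", "AB", "B", "O")),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(blood_compatible("AB", c("AB", "A")), c(TRUE, FALSE))
})

test_that("high-MELD 2B overtakes low-MELD 2A only under the MELD system", {
  reg <- rbind(
    make_registry(1, meld = 22, ctp_score = 11L, icu = TRUE, life7 = TRUE,
                  hrs = TRUE, follow_up = 30),   # status 2A, MELD 22
    make_registry(1, meld = 36, ctp_score = 10L, follow_up = 30))  # 2B, 36
  reg$id <- c("low_meld_2A", "high_meld_2B")
  offer <- donor_offer(1, "O")
  old <- rank_waitlist(reg, offer, system = "ctp_status")
  expect_equal(old$id, c("low_meld_2A", "high_meld_2B"))
  new <- rank_waitlist(reg, offer, system = "meld")
  expect_equal(new$id, c("high_meld_2B", "low_meld_2A"))
})

test_that("queue ordering is a stable total order with the stated tie-breaks", {
  set.seed(61)
  n <- 80
  reg <- make_registry(n, meld = sample(6:40, n, TRUE),
                       ctp_score = sample(7:15, n, TRUE),
                       hcc = runif(n) < 0.4,
                       region = sample(1:3, n, TRUE),
                       follow_up = sample(1:900, n),
                       blood = sample(c("A", "B", "AB", "O"), n, TRUE))
  offer <- donor_offer(2, "A")
  ranked <- rank_waitlist(reg, offer, system = "meld")
  # permutation of the compatibility-filtered input
  keep <- reg$id[blood_compatible("A", reg$blood_type)]
  expect_setequal(ranked$id, keep)
  expect_equal(anyDuplicated(ranked$id), 0L)
  # stability: shuffling the input changes nothing
  ranked2 <- rank_waitlist(reg[sample(n), ], offer, system = "meld")
  expect_equal(ranked2$id, ranked$id)
  # tiers weakly increase down the queue; within tier MELD weakly decreases
  expect_true(all(diff(ranked$tier_rank) >= 0))
  same_tier <- diff(ranked$tier_rank) == 0
  expect_true(all(diff(ranked$allocation_meld)[same_tier] <= 0))
  # equal tier and MELD: longer waiting first
  key_ties <- same_tier & diff(ranked$allocation_meld) == 0
  expect_true(all(diff(ranked$follow_up_days)[key_ties] <= 0))
})

test_that("the 38-40 tier orders by exact score with the regional leg first", {
  reg <- make_registry(6, meld = c(38, 38, 39, 39, 40, 40),
                       ctp_score = 10L, region = c(1, 2, 1, 2, 1, 2),
                       follow_up = 10)
  reg$id <- c("38R", "38N", "39R", "39N", "40R", "40N")
  ranked <- rank_waitlist(reg, donor_offer(1, "O"), system = "meld")
  expect_equal(ranked$id, c("40R", "40N", "39R", "39N", "38R", "38N"))
  expect_true(all(ranked$tier_rank == 2L))
})

test_that("HCC exception points enter the queue before tier assignment", {
  reg <- make_registry(2, meld = c(18, 20), hcc = c(TRUE, FALSE),
                       hcc_stage = c("T2", NA), ctp_score = 10L,
                       follow_up = 10)
  reg$id <- c("hcc18", "non20")
  ranked <- rank_waitlist(reg, donor_offer(1, "O"), system = "meld")
  # 18 + 5 = 23 beats 20, and moves up a tier row
  expect_equal(ranked$id, c("hcc18", "non20"))
  expect_equal(ranked$allocation_meld, c(23L, 20L))
  expect_equal(ranked$tier_rank, c(5L, 7L))
})

test_that("previous system grants national reach to urgent statuses briefly", {
  reg <- rbind(
    make_registry(1, meld = 25, ctp_score = 11L, icu = TRUE, life7 = TRUE,
                  hrs = TRUE, region = 2L, follow_up = 7),    # 2A, 7 days
    make_registry(1, meld = 25, ctp_score = 11L, icu = TRUE, life7 = TRUE,
                  hrs = TRUE, region = 2L, follow_up = 60),   # 2A, stale
    make_registry(1, meld = 25, ctp_score = 10L, region = 1L,
                  follow_up = 400))                           # regional 2B
  reg$id <- c("2A_fresh_far", "2A_stale_far", "2B_home")
  ranked <- rank_waitlist(reg, donor_offer(1, "O"), system = "ctp_status")
  # fresh 2A reaches nationally and wins; stale 2A loses its reach but
  # still outranks lower urgency; the regional 2B follows
  expect_equal(ranked$id, c("2A_fresh_far", "2A_stale_far", "2B_home"))
  expect_error(rank_waitlist(reg[0, ], donor_offer(1, "O")), "empty")
})
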