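#' Donor-recipient ABO compatibility
#'
#' Identical-or-compatible rule with no sub-prioritization: O donors match
#' all recipients; A matches A and AB; B matches B and AB; AB matches AB.
#'
#' @param donor Donor blood type ("A", "B", "AB", "O").
#' @param recipient Recipient blood type(s). Vectorized.
#' @return Logical vector.
#' @export
blood_compatible <- function(donor, recipient) {
  ok <- list(O = c("A", "B", "AB", "O"), A = c("A", "AB"),
             B = c("B", "AB"), AB = "AB")
  if (!donor %in% names(ok)) stop("invalid donor blood type", call. = FALSE)
  recipient %in% ok[[donor]]
}

#' A deceased-donor organ offer
#'
#' @param donor_region Donor hospital region (1, 2 or 3).
#' @param blood_type Donor ABO type.
#' @return Object of class \code{donor_offer}.
#' @export
donor_offer <- function(donor_region, blood_type) {
  if (!donor_region %in% 1:3) stop("region must be 1, 2 or 3", call. = FALSE)
  if (!blood_type %in% c("A", "B", "AB", "O"))
    stop("invalid blood type", call. = FALSE)
  structure(list(donor_region = as.integer(donor_region),
                 blood_type = blood_type), class = "donor_offer")
}

tier_labels <- function() {
  c("combined regional and national status 1",
    "regional/national MELD 38-40 (regional then national per score)",
    "regional MELD 31-37", "national MELD 31-37",
    "regional MELD 21-30", "national MELD 21-30",
    "regional MELD <=20", "national MELD <=20")
}

#' Assign the Korean staged broader-sharing allocation tier
#'
#' Implements the KONOS staged model: status 1 candidates share one combined
#' regional+national tier; MELD 38-40 candidates form the national
#' broader-sharing tier (offers made regionally then nationally for each
#' score); lower bands alternate regional before national rows (31-37, then
#' 21-30, then <= 20).
#'
#' @param status Previous-system status (only \code{"1"} is special here).
#' @param allocation_meld Integer allocation MELD (after any HCC exception),
#'   in [6, 40].
#' @param candidate_region,donor_region Regions in \{1, 2, 3\}.
#' @return data.frame(rank, label) with rank in 1..8.
#' @export
assign_tier <- function(status, allocation_meld, candidate_region,
                        donor_region) {
  n <- max(length(status), length(allocation_meld), length(candidate_region))
  status <- rep_len(as.character(status), n)
  allocation_meld <- rep_len(allocation_meld, n)
  candidate_region <- rep_len(candidate_region, n)
  if (any(!candidate_region %in% 1:3) || !all(donor_region %in% 1:3))
    stop("invalid region", call. = FALSE)
  if (any(allocation_meld < 6 | allocation_meld > 40))
    stop("allocation_meld must be in [6, 40]", call. = FALSE)
  regional <- candidate_region == donor_region
  rank <- ifelse(status == "1", 1L,
          ifelse(allocation_meld >= 38, 2L,
          ifelse(allocation_meld >= 31, ifelse(regional, 3L, 4L),
          ifelse(allocation_meld >= 21, ifelse(regional, 5L, 6L),
                 ifelse(regional, 7L, 8L)))))
  data.frame(rank = as.integer(rank), label = tier_labels()[rank])
}

#' Rank a waitlist for a donor offer
#'
#' Orders ABO-compatible candidates for one organ under either system.
#' \describe{
#'   \item{\code{"meld"}}{the KONOS staged model: (tier rank, allocation
#'     MELD descending, regional leg before national within the 38-40 tier
#'     at each score, waiting time descending). HCC exception points are
#'     applied before tier assignment.}
#'   \item{\code{"ctp_status"}}{the previous system: status urgency
#'     1 > 2A > 2B > 3, with national reach only for status 1/2A within
#'     \code{national_window_days} of registration (other-region candidates
#'     without reach rank after all candidates with access), then waiting
#'     time descending.}
#' }
#' Waiting time is taken from \code{follow_up_days}. The ordering is total
#' and stable: the result is a permutation of the compatibility-filtered
#' input, invariant to input order.
#'
#' @param registry A \code{liver_registry} data.frame.
#' @param offer A \code{\link{donor_offer}}.
#' @param system \code{"meld"} or \code{"ctp_status"}.
#' @param exception_table HCC exception table for the MELD system.
#' @param national_window_days National-priority window for status 1/2A
#'   under the previous system (default 14 days from registration).
#' @return The compatible candidates, ordered, with columns
#'   \code{allocation_meld}, \code{status}, \code{tier_rank},
#'   \code{tier_label}, and \code{queue_position} prepended to the registry
#'   fields.
#' @export
rank_waitlist <- function(registry, offer, system = c("meld", "ctp_status"),
                          exception_table = konos_exception_table(),
                          national_window_days = 14) {
  system <- match.arg(system)
  if (!nrow(registry)) stop("empty candidate list", call. = FALSE)
  reg <- add_status(add_meld(registry))
  reg <- reg[blood_compatible(offer$blood_type, reg$blood_type), ,
             drop = FALSE]
  if (!nrow(reg)) return(reg)
  reg$allocation_meld <- apply_exception(reg$meld, reg$hcc, exception_table)
  waiting <- reg$follow_up_days
  # candidate id as final key makes the order total (hence stable under
  # input permutation) even for exact ties
  if (system == "meld") {
    tier <- assign_tier(reg$status, reg$allocation_meld, reg$region,
                        offer$donor_region)
    reg$tier_rank <- tier$rank
    reg$tier_label <- tier$label
    t2_national <- as.integer(tier$rank == 2L &
                              reg$region != offer$donor_region)
    ord <- order(reg$tier_rank, -reg$allocation_meld, t2_national,
                 -waiting, reg$id, method = "radix")
  } else {
    urgency <- as.integer(factor(reg$status,
                                 levels = c("1", "2A", "2B", "3",
                                            "unlisted")))
    regional <- reg$region == offer$donor_region
    access <- regional | (reg$status %in% c("1", "2A") &
                          waiting <= national_window_days)
    reg$tier_rank <- urgency
    reg$tier_label <- paste0("status ", reg$status,
                             ifelse(access, "", " (no regional access)"))
    ord <- order(urgency, !access, -waiting, reg$id, method = "radix")
  }
  reg <- reg[ord, , drop = FALSE]
  reg$queue_position <- seq_len(nrow(reg))
  rownames(reg) <- NULL
  reg
}
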