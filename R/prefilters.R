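#' Expected background dose accrued between two reads
#'
#' A worn dosimeter integrates ambient background radiation between its
#' previous read (`day1`) and the current one (`day2`); that accrual is
#' subtracted before any reporting decision. The accrual is linear in elapsed
#' time at `radiation_per_week` mrem per week, with elapsed weeks kept as a
#' real number. Any value below 1 mrem — including the negative values that
#' arise when the recorded previous read date lies after the current one — is
#' floored to 1 mrem, and missing dates fall back to the same 1 mrem floor
#' with a warning.
#'
#' @param day1 Previous read date (anything `as.Date` accepts, or `NA`).
#' @param day2 Current read date.
#' @param radiation_per_week Weekly background accrual in mrem/week; must be
#'   positive.
#' @return A list of class `background_result` with fields `bgd` (mrem, >= 1)
#'   and `elapsed_days` (possibly `NA`). The background is kept with the
#'   dosimeter so it can be added back to reported doses downstream.
#' @examples
#' compute_background(Sys.Date() - 7, Sys.Date())$bgd   # one week -> 1 mrem
#' @export
compute_background <- function(day1, day2, radiation_per_week = 1) {
  stopifnot(radiation_per_week > 0)
  day1 <- as.Date(day1)
  day2 <- as.Date(day2)
  if (is.na(day1) || is.na(day2)) {
    warning("missing read date(s); background floored to 1 mrem")
    return(structure(list(bgd = 1, elapsed_days = NA_real_),
                     class = "background_result"))
  }
  elapsed <- as.numeric(day2 - day1)
  bgd <- radiation_per_week * elapsed / 7
  if (bgd < 1) bgd <- 1
  structure(list(bgd = bgd, elapsed_days = elapsed),
            class = "background_result")
}

#' Subtract accrued background from a dosimeter's element doses
#'
#' Reduces every element dose by the accrued background, flooring at zero
#' (negative physical doses are meaningless). The original doses are retained
#' in the record for audit.
#'
#' @param record A [dosimeter_record].
#' @param bgd A `background_result` from [compute_background], or a single
#'   number of mrem.
#' @return The record with `element_doses` reduced, plus fields
#'   `raw_element_doses` (the doses before subtraction) and `bgd` (the mrem
#'   value subtracted).
#' @export
subtract_background <- function(record, bgd) {
  stopifnot(inherits(record, "dosimeter_record"))
  amount <- if (inherits(bgd, "background_result")) bgd$bgd else as.numeric(bgd)
  record$raw_element_doses <- record$element_doses
  record$element_doses <- pmax(record$element_doses - amount, 0)
  record$bgd <- amount
  record
}

#' Reporting-level filter for low-dose dosimeters
#'
#' Most dosimeters belong to workers who were not measurably exposed; those
#' are removed before any shape analysis. After background subtraction, each
#' element dose below its per-element threshold (`Threshold1..Threshold3`,
#' `ThresholdNeut`) is zeroed, and the dosimeter is filtered out when the
#' remaining total is at most `low_dose_cut` (16 mrem by default, i.e. the
#' total would stay below the 20 mrem reporting level once the typical
#' background is added back).
#'
#' @param record A [dosimeter_record] whose doses are already
#'   background-subtracted.
#' @param config A [gc_config].
#' @return A list with `decision` (`"filtered_out"` or `"retained"`),
#'   `total_dose` (mrem after element zeroing) and `zeroed_elements` (indices
#'   of elements zeroed by their per-element threshold).
#' @export
low_dose_filter <- function(record, config = gc_config()) {
  stopifnot(inherits(record, "dosimeter_record"))
  doses <- record$element_doses
  thresholds <- c(config$Threshold1, config$Threshold2, config$Threshold3,
                  config$ThresholdNeut)[seq_along(doses)]
  zeroed <- which(doses < thresholds)
  doses[zeroed] <- 0
  total <- sum(doses)
  list(
    decision = if (total <= config$low_dose_cut) "filtered_out" else "retained",
    total_dose = total,
    zeroed_elements = zeroed
  )
}

#' Crystal dose spread check
#'
#' First plausibility condition on the element doses: the relative spread
#' `(max - min) / max` over the present elements must stay below
#' `Crystals_Quotient`. A genuinely exposed dosimeter has roughly concordant
#' element responses; a large spread flags either an exotic radiation field
#' (checked next against the ratio table) or a bad read.
#'
#' @param doses Numeric vector of 3 or 4 element doses in mrem.
#' @param quotient Maximum allowed relative spread, in `[0, 1]`.
#' @return `TRUE` (pass) or `FALSE`. A zero maximum dose fails (the spread is
#'   undefined), routing the dosimeter towards manual review.
#' @examples
#' crystal_spread_check(c(10, 10, 10, 10), 0.25)  # TRUE, spread 0
#' crystal_spread_check(c(10, 10, 10, 5), 0.25)   # FALSE, spread 0.5
#' @export
crystal_spread_check <- function(doses, quotient = gc_config()$Crystals_Quotient) {
  stopifnot(length(doses) >= 3)
  mx <- max(doses)
  if (mx <= 0) return(FALSE)
  (mx - min(doses)) / mx < quotient
}

# The four tabulated dose ratios, as numerator/denominator element indices.
RATIO_DEFS <- list(
  l4_over_l3 = c(4L, 3L),
  l3_over_l1 = c(3L, 1L),
  l3_over_l2 = c(3L, 2L),
  l1_over_l4 = c(1L, 4L)
)

#' Match element dose ratios against the radiation-field table
#'
#' Second plausibility condition: the dose ratios L4/L3, L3/L1, L3/L2 and
#' L1/L4 (restricted to the elements actually present) are compared against
#' every row of the radiation-field [ratio_table]. A row matches when every
#' computable ratio lies within `tol` (absolute) of the row's value; a ratio
#' whose denominator is zero can only match the table's sentinel magnitudes
#' (values above `1/tol`), and a 0/0 ratio is skipped.
#'
#' @param doses Numeric vector of 3 (L1..L3) or 4 (L1..L4) element doses.
#' @param table A [ratio_table] data frame.
#' @param tol Absolute tolerance on each ratio.
#' @return A list with `beam` (the first matching row's beam name, or `NA`),
#'   `matches` (beam names of all matching rows, in table order) and `ratios`
#'   (the computed ratios, `NA` where not computable).
#' @examples
#' ratio_table_match(c(1, 1, 1, 1), tol = 0.05)$matches
#' @export
ratio_table_match <- function(doses, table = ratio_table(),
                              tol = gc_config()$ratio_table_threshold) {
  n <- length(doses)
  stopifnot(n >= 3)
  ratios <- vapply(RATIO_DEFS, function(idx) {
    if (any(idx > n)) return(NA_real_)       # L4 absent on 3-element cards
    num <- doses[idx[1]]; den <- doses[idx[2]]
    if (den == 0) {
      if (num == 0) NA_real_ else Inf
    } else num / den
  }, numeric(1))

  row_matches <- function(row_vals) {
    ok <- TRUE
    for (k in seq_along(ratios)) {
      r <- ratios[k]
      if (is.na(r)) next                     # not computable: skipped
      v <- row_vals[k]
      if (is.infinite(r)) {
        if (!(is.finite(v) && tol > 0 && v > 1 / tol)) ok <- FALSE
      } else if (abs(r - v) > tol) ok <- FALSE
      if (!ok) break
    }
    ok
  }

  vals <- as.matrix(table[names(RATIO_DEFS)])
  hit <- vapply(seq_len(nrow(table)), function(i) row_matches(vals[i, ]),
                logical(1))
  list(
    beam = if (any(hit)) table$beam[which(hit)[1]] else NA_character_,
    matches = table$beam[hit],
    ratios = ratios
  )
}

#' Integral-ratio plausibility filter
#'
#' Combines the two element-dose plausibility conditions: a dosimeter
#' proceeds to shape classification when its dose spread passes
#' [crystal_spread_check] or, failing that, when its dose ratios match some
#' row of the radiation-field table ([ratio_table_match]). Otherwise it is
#' routed to manual review.
#'
#' @param record A background-subtracted [dosimeter_record] that survived the
#'   low-dose and shape filters.
#' @param config A [gc_config].
#' @param table A [ratio_table] data frame.
#' @return A list with `decision` (`"proceed"` or `"manual_review"`),
#'   `spread_pass` (logical) and `beam` (matched beam name or `NA`).
#' @export
prefilter_dosimeter <- function(record, config = gc_config(),
                                table = ratio_table()) {
  doses <- record$element_doses
  spread <- crystal_spread_check(doses, config$Crystals_Quotient)
  if (spread)
    return(list(decision = "proceed", spread_pass = TRUE, beam = NA_character_))
  m <- ratio_table_match(doses, table, config$ratio_table_threshold)
  list(
    decision = if (!is.na(m$beam)) "proceed" else "manual_review",
    spread_pass = FALSE,
    beam = m$beam
  )
}
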