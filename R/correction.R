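#' Correct an elevated-background (class A) glow curve
#'
#' Class A anomalies are the one class with a straightforward automatic fix:
#' the parasitic signal sits at a temperature end the dosimetric peak does
#' not occupy, so the affected channels are cut to zero and the dose
#' recomputed from the remaining integral. `A_LOW` cuts channels
#' `1..LowCutCh`; `A_HIGH` cuts `HighCutCh..200`; both cuts apply when both
#' sub-classes hold. Channels outside the cut ranges are bit-identical to
#' the input, and a correction can never increase the dose.
#'
#' @param gc The [glow_curve] to correct.
#' @param labels Non-empty subset of `c("A_LOW", "A_HIGH")`; anything else is
#'   an error, since only class A is correctable.
#' @param config A [gc_config]; supplies the cut boundaries and dose
#'   calibration.
#' @param dosimeter_id Carried into the proposal for reporting.
#' @return A list with `curve` (the corrected [glow_curve]) and `proposal`
#'   (a `correction_proposal`: sub-class, cut channel ranges, dose before and
#'   after in mrem, and status `"suggested"`).
#' @export
correct_class_a <- function(gc, labels, config = gc_config(),
                            dosimeter_id = NA_character_) {
  if (length(labels) == 0 || !all(labels %in% c("A_LOW", "A_HIGH")))
    stop("automatic correction is only possible for class A (A_LOW/A_HIGH) curves")
  ch <- as.numeric(gc)
  dose_before <- recompute_dose(gc, config$dose_calibration)
  cuts <- list()
  if ("A_LOW" %in% labels) {
    ch[1:config$LowCutCh] <- 0
    cuts <- c(cuts, list(c(1L, as.integer(config$LowCutCh))))
  }
  if ("A_HIGH" %in% labels) {
    ch[config$HighCutCh:GC_CHANNELS] <- 0
    cuts <- c(cuts, list(c(as.integer(config$HighCutCh), GC_CHANNELS)))
  }
  corrected <- glow_curve(ch)
  dose_after <- recompute_dose(corrected, config$dose_calibration)
  proposal <- structure(list(
    dosimeter_id = dosimeter_id,
    sub_class = if (length(labels) == 2) "both" else labels,
    cut_channels = cuts,
    dose_before = dose_before,
    dose_after = dose_after,
    status = "suggested"
  ), class = "correction_proposal")
  list(curve = corrected, proposal = proposal)
}

#' @export
print.correction_proposal <- function(x, ...) {
  cat("<correction_proposal>", x$sub_class, "cut;",
      sprintf("dose %.2f -> %.2f mrem [%s]\n",
              x$dose_before, x$dose_after, x$status))
  invisible(x)
}

#' Recompute the dose from a glow-curve integral
#'
#' The absorbed dose is proportional to the emitted light, i.e. to the sum
#' of the channel intensities.
#'
#' @param gc A [glow_curve].
#' @param calibration mrem per unit of curve integral; > 0.
#' @return Dose in mrem.
#' @export
recompute_dose <- function(gc, calibration = gc_config()$dose_calibration) {
  stopifnot(calibration > 0)
  calibration * sum(as.numeric(gc))
}

#' Apply a correction or queue it for technician approval
#'
#' With `bFullAutomated` true the proposal is applied without approval;
#' otherwise it stays `"suggested"` and appears in the report queue. A
#' dosimeter whose pre-correction dose exceeds `ManualReviewThreshold` is
#' never auto-applied, regardless of the flag. Applying an already-applied
#' proposal is a no-op.
#'
#' @param proposal A `correction_proposal` from [correct_class_a].
#' @param b_full_automated The `bFullAutomated` flag.
#' @param config A [gc_config]; supplies `ManualReviewThreshold`.
#' @return The proposal with `status` set to `"applied"` or `"suggested"`.
#' @export
apply_or_suggest <- function(proposal, b_full_automated = gc_config()$bFullAutomated,
                             config = gc_config()) {
  stopifnot(inherits(proposal, "correction_proposal"))
  if (identical(proposal$status, "applied")) return(proposal)
  proposal$status <-
    if (isTRUE(b_full_automated) &&
        proposal$dose_before <= config$ManualReviewThreshold)
      "applied" else "suggested"
  proposal
}
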