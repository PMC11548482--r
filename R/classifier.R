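#' Detect spikes in a glow curve
#'
#' Spikes — typically one or two channels wide — are sharp excursions caused
#' by static electricity, burning dust particles or electronic interference.
#' A channel index `i` (1..197) fires when the rise into channel `i+1`
#' exceeds `spike_neigh_diff` percent of channel `i` AND the curve falls away
#' just as sharply on the other side within two channels:
#'
#'   `Ch[i+1] > Ch[i] * (100 + S)/100`  and
#'   (`Ch[i+1] > Ch[i+2] * (100 + S)/100` or `Ch[i+2] > Ch[i+3] * (100 + S)/100`)
#'
#' Adjacent firing indices are merged into a single spike event, so one
#' physical spike counts once.
#'
#' @param gc A [glow_curve].
#' @param spike_neigh_diff Percent jump between neighbouring channels that
#'   counts as a spike edge.
#' @return A list of class `spike_report`: `positions` (firing indices `i`,
#'   strictly increasing, each in 1..197), `count` (number of merged spike
#'   events), and `wide` (logical per firing index: `TRUE` when only the
#'   two-channel-wide condition fired, so channel `i+2` is part of the spike).
#' @export
detect_spikes <- function(gc, spike_neigh_diff = gc_config()$SpikeNeighDiff) {
  ch <- as.numeric(gc)
  f <- (100 + spike_neigh_diff) / 100
  i <- seq_len(GC_CHANNELS - 3L)            # 1..197
  cond1 <- ch[i + 1L] > ch[i] * f
  cond2 <- ch[i + 1L] > ch[i + 2L] * f
  cond3 <- ch[i + 2L] > ch[i + 3L] * f
  fired <- cond1 & (cond2 | cond3)
  pos <- which(fired)
  # runs of adjacent indices = one spike event each
  n_events <- if (length(pos)) sum(diff(c(-10L, pos)) > 1L) else 0L
  structure(list(
    positions = pos,
    count = n_events,
    wide = !cond2[pos] & cond3[pos]
  ), class = "spike_report")
}

#' @export
print.spike_report <- function(x, ...) {
  cat("<spike_report>", x$count, "spike event(s) at i =",
      paste(x$positions, collapse = ", "), "\n")
  invisible(x)
}

#' Class D decision: too many spikes
#'
#' A curve is class D when strictly more than `n_spikes` spike events were
#' found. Class D preempts every other class: a spiky curve is not smoothed
#' or classified further.
#'
#' @param report A `spike_report` from [detect_spikes].
#' @param n_spikes Spike-count threshold.
#' @return `TRUE` when the curve is class D.
#' @export
classify_class_d <- function(report, n_spikes = gc_config()$NSpikes) {
  report$count > n_spikes
}

#' Remove detected spikes by local interpolation
#'
#' For a curve with at most `NSpikes` spike events, the channels implicated
#' by each event — channel `i+1`, plus `i+2` when only the two-channel-wide
#' condition fired — are replaced by linear interpolation between the nearest
#' untouched neighbours. Every other channel is bit-identical to the input,
#' which keeps the downstream window averages auditable.
#'
#' @param gc A [glow_curve].
#' @param report A `spike_report` for `gc`; recomputed when omitted.
#' @param spike_neigh_diff Used only when `report` is omitted.
#' @return A [glow_curve] with spike channels interpolated.
#' @export
smoothen <- function(gc, report = NULL,
                     spike_neigh_diff = gc_config()$SpikeNeighDiff) {
  if (is.null(report)) report <- detect_spikes(gc, spike_neigh_diff)
  ch <- as.numeric(gc)
  if (!length(report$positions)) return(glow_curve(ch))
  bad <- unique(sort(c(report$positions + 1L,
                       (report$positions + 2L)[report$wide])))
  bad <- bad[bad <= GC_CHANNELS]
  # interpolate each run of bad channels between its untouched neighbours
  runs <- split(bad, cumsum(c(1L, diff(bad) > 1L)))
  for (run in runs) {
    lo <- min(run) - 1L
    hi <- max(run) + 1L
    left  <- if (lo >= 1L) ch[lo] else NA_real_
    right <- if (hi <= GC_CHANNELS) ch[hi] else NA_real_
    if (is.na(left))  left  <- right
    if (is.na(right)) right <- left
    ch[run] <- left + (right - left) * (run - lo) / (hi - lo)
  }
  glow_curve(pmax(ch, 0))
}

# Index of the curve maximum; ties break to the lowest channel.
gc_argmax <- function(gc) which.max(as.numeric(gc))

#' Class A: elevated background at the low or high temperature end
#'
#' With the curve maximum in place (within `MaxAllowedShift` channels of
#' channel 95), an elevated but sub-dominant plateau over a temperature-end
#' window indicates residual or parasitic signal. The window average must lie
#' strictly between `MinBgdHeight` and `MaxBgdHeight` percent of the curve
#' maximum: above the lower bound it is no longer instrument noise, below the
#' upper bound it is background rather than the glow peak itself. The high
#' window (`BgdHTTLChLow..BgdHTTLChHigh`) yields sub-class `A_HIGH`, the low
#' window (`BgdLTTLChLow..BgdLTTLChHigh`) yields `A_LOW`; both can hold
#' simultaneously.
#'
#' @param gc A smoothed [glow_curve].
#' @param config A [gc_config].
#' @return Character vector: a subset of `c("A_LOW", "A_HIGH")`, empty when
#'   class A does not apply (including when the peak-position precondition
#'   fails).
#' @export
classify_class_a <- function(gc, config = gc_config()) {
  ch <- as.numeric(gc)
  mx <- max(ch)
  chmax <- gc_argmax(gc)
  if (abs(chmax - config$expected_peak_channel) > config$MaxAllowedShift)
    return(character())
  lo_bound <- 0.01 * config$MinBgdHeight * mx
  hi_bound <- 0.01 * config$MaxBgdHeight * mx
  in_band <- function(from, to) {
    avg <- mean(ch[from:to])
    avg > lo_bound && avg < hi_bound
  }
  labels <- character()
  if (in_band(config$BgdLTTLChLow, config$BgdLTTLChHigh))
    labels <- c(labels, "A_LOW")
  if (in_band(config$BgdHTTLChLow, config$BgdHTTLChHigh))
    labels <- c(labels, "A_HIGH")
  labels
}

#' Class C: glow peak shifted in temperature
#'
#' The dosimetric peak of this card type sits at channel 95; a maximum more
#' than `max_allowed_shift` channels away indicates a heating-profile or
#' timing problem. Above the interval the curve is `C_HIGH`, below it
#' `C_LOW`.
#'
#' @param gc A smoothed [glow_curve].
#' @param max_allowed_shift Allowed shift in channels.
#' @param expected_peak Channel of the nominal peak (95).
#' @return `"C_HIGH"`, `"C_LOW"`, or empty character when the peak is inside
#'   the allowed interval.
#' @export
classify_class_c <- function(gc, max_allowed_shift = gc_config()$MaxAllowedShift,
                             expected_peak = EXPECTED_PEAK_CHANNEL) {
  chmax <- gc_argmax(gc)
  if (chmax > expected_peak + max_allowed_shift) return("C_HIGH")
  if (chmax < expected_peak - max_allowed_shift) return("C_LOW")
  character()
}

#' Class B: abnormal glow-curve width
#'
#' With the peak in place, a curve is `B_WIDE` when the average over the
#' central window `TLDWideLowCh..TLDWideHighCh` exceeds `WideAvgVal` percent
#' of the maximum — the glow peak fills the window instead of standing out of
#' it. Failing that, it is `B_NARROW` when both flanks beyond
#' `half_width_num_ch` channels of the maximum (`1..Chmax-h` and
#' `Chmax+h..200`) average below `NarrowAvgVal` percent of the maximum — the
#' curve is close to a delta. A flank window that is empty (the peak sits
#' within `h` channels of the curve edge) is treated as vacuously satisfied.
#'
#' @param gc A smoothed [glow_curve].
#' @param config A [gc_config].
#' @return `"B_WIDE"`, `"B_NARROW"`, or empty character.
#' @export
classify_class_b <- function(gc, config = gc_config()) {
  ch <- as.numeric(gc)
  mx <- max(ch)
  chmax <- gc_argmax(gc)
  if (abs(chmax - config$expected_peak_channel) > config$MaxAllowedShift)
    return(character())
  if (mean(ch[config$TLDWideLowCh:config$TLDWideHighCh]) >
      0.01 * config$WideAvgVal * mx)
    return("B_WIDE")
  h <- config$half_width_num_ch
  narrow_bound <- 0.01 * config$NarrowAvgVal * mx
  left_hi <- chmax - h
  right_lo <- chmax + h
  left_ok  <- left_hi < 1L || mean(ch[1:left_hi]) < narrow_bound
  right_ok <- right_lo > GC_CHANNELS ||
    mean(ch[right_lo:GC_CHANNELS]) < narrow_bound
  if (left_ok && right_ok) return("B_NARROW")
  character()
}

#' Classify one glow curve through the anomaly rule cascade
#'
#' Runs the full cascade on a curve that the upstream filters already flagged
#' as suspect: class D first (on the raw curve; spiky curves are classified
#' immediately and never smoothed), then spike smoothing, then classes A, C
#' and B in order, and finally the residual class E for anomalies matching no
#' other rule. Classes A, B, C and E are mutually exclusive; the two class-A
#' sub-classes can co-occur.
#'
#' @param gc A [glow_curve].
#' @param config A [gc_config].
#' @return A list of class `gc_classification`: `labels` (character vector of
#'   assigned labels), `spike_report`, `smoothed` (the curve the post-D
#'   stages saw), and `trace` (named logical vector of each stage's
#'   decision, for audit).
#' @examples
#' gc <- generate_normal_gc(seed = 1, noise_cv = 0)
#' classify_gc(inject_anomaly(gc, anomaly_spec("C_HIGH"), seed = 1))$labels
#' @export
classify_gc <- function(gc, config = gc_config()) {
  report <- detect_spikes(gc, config$SpikeNeighDiff)
  trace <- c(class_d = FALSE, class_a = FALSE, class_c = FALSE,
             class_b = FALSE, class_e = FALSE)
  if (classify_class_d(report, config$NSpikes)) {
    trace["class_d"] <- TRUE
    return(structure(list(labels = "D", spike_report = report,
                          smoothed = gc, trace = trace),
                     class = "gc_classification"))
  }
  sm <- smoothen(gc, report)
  labels <- classify_class_a(sm, config)
  if (length(labels)) {
    trace["class_a"] <- TRUE
  } else {
    labels <- classify_class_c(sm, config$MaxAllowedShift,
                               config$expected_peak_channel)
    if (length(labels)) {
      trace["class_c"] <- TRUE
    } else {
      labels <- classify_class_b(sm, config)
      if (length(labels)) {
        trace["class_b"] <- TRUE
      } else {
        labels <- "E"
        trace["class_e"] <- TRUE
      }
    }
  }
  structure(list(labels = labels, spike_report = report, smoothed = sm,
                 trace = trace),
            class = "gc_classification")
}

#' @export
print.gc_classification <- function(x, ...) {
  cat("<gc_classification>", paste(x$labels, collapse = "+"),
      sprintf("(%d spike event(s))\n", x$spike_report$count))
  invisible(x)
}
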