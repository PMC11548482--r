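#' glowqc: quality control of TLD glow curves
#'
#' Staged quality control of thermoluminescent dosimeter (TLD) glow curves:
#' background subtraction, reporting-level filtering, a shallow neural-network
#' shape filter, crystal dose-ratio plausibility checks, a rule cascade over
#' five anomaly classes, automatic correction of elevated-background curves,
#' and per-dosimeter statistics. A synthetic glow-curve simulator with labeled
#' anomaly injection stands in for reader databases during training and
#' testing.
#'
#' @keywords internal
"_PACKAGE"

# Number of photomultiplier channels in a digitized glow curve.
GC_CHANNELS <- 200L

# Channel at which the dosimetric glow peak of LiF:Mg,Ti appears under the
# 25 C/s heating profile (about 205 C). The shift and width rules are
# anchored to this channel, so it is a constant, not a configuration knob.
EXPECTED_PEAK_CHANNEL <- 95L

# The eight anomaly labels of the rule cascade.
GC_LABELS <- c("A_LOW", "A_HIGH", "B_WIDE", "B_NARROW",
               "C_LOW", "C_HIGH", "D", "E")

#' Construct a glow curve
#'
#' A glow curve is the photomultiplier current of a heated TLD element
#' digitized into 200 channels (arbitrary current units). Channel indices are
#' 1-based and inclusive throughout the package.
#'
#' @param channels Numeric vector of exactly 200 finite, non-negative
#'   intensities.
#' @return An object of class `glow_curve` (a numeric vector with a class
#'   attribute).
#' @examples
#' gc <- glow_curve(dnorm(1:200, 95, 8))
#' which.max(gc)
#' @export
glow_curve <- function(channels) {
  channels <- as.numeric(channels)
  if (length(channels) != GC_CHANNELS)
    stop("a glow curve must have exactly ", GC_CHANNELS, " channels, got ",
         length(channels))
  if (anyNA(channels) || any(!is.finite(channels)))
    stop("glow curve intensities must be finite")
  if (any(channels < 0))
    stop("glow curve intensities must be non-negative")
  structure(channels, class = "glow_curve")
}

#' @export
print.glow_curve <- function(x, ...) {
  cat("<glow_curve> 200 channels, max", format(max(x), digits = 4),
      "at channel", which.max(x), "\n")
  invisible(x)
}

#' @param x,y,... Standard plotting arguments.
#' @rdname glow_curve
#' @export
plot.glow_curve <- function(x, y, ...,
                            map = channel_temperature_map(),
                            xlab = "Temperature (°C)",
                            ylab = "Intensity (a.u.)", type = "l") {
  graphics::plot(channel_temperature(seq_len(GC_CHANNELS), map),
                 as.numeric(x), xlab = xlab, ylab = ylab, type = type, ...)
  invisible(x)
}

is_glow_curve <- function(x) inherits(x, "glow_curve")

#' Channel-to-temperature mapping
#'
#' Linear display mapping from channel index to element temperature. The
#' defaults place channel 95 at 205 degrees C, the dosimetric peak position of
#' LiF:Mg,Ti at 25 C/s heating. The mapping is used for display only; no
#' classifier depends on temperature.
#'
#' @param t0 Temperature offset in degrees C.
#' @param dt Degrees per channel; must be positive so the map is strictly
#'   increasing.
#' @return A `channel_temperature_map` object.
#' @export
channel_temperature_map <- function(t0 = 15, dt = 2) {
  stopifnot(is.numeric(t0), is.numeric(dt), dt > 0)
  structure(list(t0 = t0, dt = dt), class = "channel_temperature_map")
}

#' @param channel Channel index or vector of indices.
#' @param map A `channel_temperature_map`.
#' @rdname channel_temperature_map
#' @export
channel_temperature <- function(channel, map = channel_temperature_map()) {
  map$t0 + map$dt * channel
}

#' Construct a dosimeter record
#'
#' One dosimeter as read by the reader: 3 or 4 crystal elements, each with a
#' glow curve, an element dose in mrem and an element correction coefficient
#' (ECC), plus read dates and identifiers. Element 4, when present, is the
#' thermal-neutron crystal.
#'
#' @param dosimeter_id,reader_id Identifier strings.
#' @param curves List of 3 or 4 [glow_curve] objects, one per element.
#' @param element_doses Numeric vector of element doses L1..L3 or L1..L4 in
#'   mrem; same length as `curves`.
#' @param read_date Date of the current read (day2).
#' @param prev_read_date Date of the previous read (day1); may be `NA`.
#' @param ecc Per-element correction coefficients (dimensionless); recycled to
#'   the element count.
#' @return A `dosimeter_record` object.
#' @export
dosimeter_record <- function(dosimeter_id, reader_id, curves, element_doses,
                             read_date, prev_read_date = NA, ecc = 1) {
  n <- length(element_doses)
  if (!n %in% c(3L, 4L))
    stop("a dosimeter has 3 or 4 elements, got ", n)
  if (length(curves) != n)
    stop("element_doses and curves must have equal count")
  if (any(element_doses < 0)) stop("element doses must be non-negative")
  curves <- lapply(curves, function(g) if (is_glow_curve(g)) g else glow_curve(g))
  structure(list(
    dosimeter_id   = as.character(dosimeter_id),
    reader_id      = as.character(reader_id),
    curves         = curves,
    element_doses  = as.numeric(element_doses),
    read_date      = as.Date(read_date),
    prev_read_date = if (length(prev_read_date) == 1 && is.na(prev_read_date))
      as.Date(NA) else as.Date(prev_read_date),
    ecc            = rep_len(as.numeric(ecc), n)
  ), class = "dosimeter_record")
}

#' @export
print.dosimeter_record <- function(x, ...) {
  cat("<dosimeter_record>", x$dosimeter_id, "reader", x$reader_id, "\n",
      length(x$element_doses), "elements, doses (mrem):",
      paste(format(x$element_doses, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

n_elements <- function(record) length(record$element_doses)

#' The radiation-field integral ratio table
#'
#' Reference table of crystal dose ratios (L4/L3, L3/L1, L3/L2, L1/L4) for the
#' radiation fields a legitimately exposed dosimeter can have seen; a
#' dosimeter whose element spread fails the quotient check must match one row
#' of this table (within a tolerance) or is routed to manual review.
#'
#' @param path Optional path to a CSV with columns
#'   `l4_over_l3,l3_over_l1,l3_over_l2,l1_over_l4,energy_kev,beam`; defaults
#'   to the packaged table of 21 fields (Cs-137, beta emitters, and N/M/H/S
#'   series X-ray qualities).
#' @return A data frame with one row per radiation field.
#' @examples
#' tab <- ratio_table()
#' tab[tab$beam == "Cs137", ]
#' @export
ratio_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ratio_table.csv", package = "glowqc",
                        mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(l4_over_l3 = "numeric",
                                        l3_over_l1 = "numeric",
                                        l3_over_l2 = "numeric",
                                        l1_over_l4 = "numeric",
                                        energy_kev = "numeric",
                                        beam = "character"))
  need <- c("l4_over_l3", "l3_over_l1", "l3_over_l2", "l1_over_l4", "beam")
  if (!all(need %in% names(tab)))
    stop("ratio table must have columns ", paste(need, collapse = ", "))
  tab
}
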