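#' Glow-peak specification for the simulator
#'
#' Peaks are modelled as asymmetric Gaussians: separate left/right standard
#' deviations `width * (1 - asymmetry)` and `width * (1 + asymmetry)`. The
#' classifiers only ever see channel statistics, so this captures the
#' morphology of real curves (a dominant dosimetric peak with minor satellite
#' peaks) without fitting first-order kinetics.
#'
#' @param center Peak channel, in 1..200.
#' @param width Width parameter in channels (standard-deviation-like); > 0.
#' @param height Peak intensity in arbitrary units; >= 0.
#' @param asymmetry Skew factor in (-1, 1); positive values stretch the
#'   high-temperature side.
#' @return A `peak_spec` list.
#' @export
peak_spec <- function(center, width, height, asymmetry = 0) {
  if (!(center >= 1 && center <= GC_CHANNELS))
    stop("peak center must lie in 1..", GC_CHANNELS)
  if (!(width > 0)) stop("peak width must be positive")
  if (!(height >= 0)) stop("peak height must be non-negative")
  if (!(abs(asymmetry) < 1)) stop("asymmetry must lie in (-1, 1)")
  structure(list(center = center, width = width, height = height,
                 asymmetry = asymmetry), class = "peak_spec")
}

#' Default normal-curve preset
#'
#' Main dosimetric peak at channel 95 with a slight high-temperature skew,
#' plus two minor satellite peaks (at 30 percent or less of the main height)
#' on either flank — the shape a good-quality read of this card type shows.
#'
#' @return List of three [peak_spec] objects.
#' @export
default_normal_peaks <- function() {
  list(
    peak_spec(center = 95,  width = 8,  height = 1000, asymmetry = 0.10),
    peak_spec(center = 60,  width = 9,  height = 250),
    peak_spec(center = 125, width = 10, height = 250)
  )
}

# Evaluate the sum of asymmetric-Gaussian peaks over the 200 channels.
gc_shape <- function(peaks) {
  x <- seq_len(GC_CHANNELS)
  y <- numeric(GC_CHANNELS)
  for (p in peaks) {
    sigma <- ifelse(x < p$center,
                    p$width * (1 - p$asymmetry),
                    p$width * (1 + p$asymmetry))
    y <- y + p$height * exp(-(x - p$center)^2 / (2 * sigma^2))
  }
  y
}

#' Generate a synthetic normal glow curve
#'
#' Builds the peak-sum shape, jitters peak heights and widths (log-normally,
#' to emulate element-to-element variation; peak centers are never jittered,
#' so the default preset keeps its maximum at channel 95), then applies
#' multiplicative Gaussian noise with coefficient of variation `noise_cv` and
#' a small additive non-negative floor.
#'
#' @param seed Integer seed, or `NULL` to draw from the current RNG state
#'   (used when a caller manages the stream, e.g. [generate_labeled_dataset]).
#' @param peaks List of [peak_spec]; defaults to [default_normal_peaks()].
#' @param noise_cv Coefficient of variation of the multiplicative channel
#'   noise; >= 0. Zero gives a noise-free curve.
#' @param shape_jitter Log-scale standard deviation of the peak height/width
#'   jitter; 0 disables it.
#' @param additive_floor Scale of the additive noise floor, as a fraction of
#'   the curve maximum.
#' @return A [glow_curve]; the (jittered) peak list is attached as attribute
#'   `"peaks"` so anomaly injection can rebuild the shape.
#' @examples
#' gc <- generate_normal_gc(seed = 7, noise_cv = 0)
#' which.max(gc)  # 95
#' @export
generate_normal_gc <- function(seed = NULL, peaks = default_normal_peaks(),
                               noise_cv = 0.05, shape_jitter = 0.1,
                               additive_floor = 0.002) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  for (p in peaks)
    if (!inherits(p, "peak_spec")) stop("peaks must be a list of peak_spec")
  if (!is.null(seed)) set.seed(seed)
  if (shape_jitter > 0) {
    peaks <- lapply(peaks, function(p) {
      p$height <- p$height * exp(stats::rnorm(1, 0, shape_jitter))
      p$width  <- p$width  * exp(stats::rnorm(1, 0, shape_jitter / 2))
      p
    })
  }
  y <- gc_shape(peaks)
  if (noise_cv > 0)
    y <- y * (1 + noise_cv * stats::rnorm(GC_CHANNELS))
  if (additive_floor > 0) {
    # dark-current pedestal: near-constant, so empty tail channels do not
    # show large *relative* channel-to-channel jumps
    base <- additive_floor * max(y)
    y <- y + base * (1 + 0.1 * stats::rnorm(GC_CHANNELS))
  }
  gc <- glow_curve(pmax(y, 0))
  attr(gc, "peaks") <- peaks
  gc
}

#' Anomaly specification for injection
#'
#' Per-label magnitude parameters, with defaults chosen so that each injected
#' anomaly is unambiguous under the default [gc_config]:
#' * `A_LOW` / `A_HIGH`: `pedestal` (fraction of the curve maximum added over
#'   `window`, defaulting to the class-A low/high windows of the config);
#' * `B_WIDE`: `width_scale` (> 1) applied to the dominant peak;
#'   `B_NARROW`: `width_scale` (< 1) applied to every peak;
#' * `C_LOW` / `C_HIGH`: `shift` in channels (sign fixed by the sub-class);
#' * `D`: `n_spikes` spikes of `spike_factor` times the local amplitude,
#'   1-2 channels wide;
#' * `E`: multiplicative ripple of amplitude `ripple_amp` and period
#'   `ripple_period` channels, resampled until the rule cascade assigns E.
#'
#' @param label One of `"A_LOW"`, `"A_HIGH"`, `"B_WIDE"`, `"B_NARROW"`,
#'   `"C_LOW"`, `"C_HIGH"`, `"D"`, `"E"`.
#' @param ... Named magnitude overrides (see above).
#' @return An `anomaly_spec` list with fields `label` and `params`.
#' @export
anomaly_spec <- function(label, ...) {
  label <- match.arg(label, GC_LABELS)
  params <- switch(label,
    A_LOW    = list(pedestal = 0.30, window = NULL),
    A_HIGH   = list(pedestal = 0.30, window = NULL),
    B_WIDE   = list(width_scale = 3),
    B_NARROW = list(width_scale = 0.25),
    C_LOW    = list(shift = 20),
    C_HIGH   = list(shift = 20),
    D        = list(n_spikes = 5, spike_factor = 3),
    E        = list(ripple_amp = 0.5, ripple_period = 30)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(params))
  if (length(unknown))
    stop("unknown magnitude parameter(s) for ", label, ": ",
         paste(unknown, collapse = ", "))
  params[names(overrides)] <- overrides
  num <- unlist(Filter(is.numeric, params))
  if (any(num <= 0)) stop("magnitude parameters must be positive")
  structure(list(label = label, params = params), class = "anomaly_spec")
}

#' Inject a labeled anomaly into a glow curve
#'
#' Applies the distortion of `spec` to `gc`. With default magnitudes, zero
#' noise and the default configuration, the rule cascade recovers the
#' injected label (the simulator-classifier consistency contract).
#'
#' Width anomalies (`B_*`) rebuild the curve from its generating peak list
#' (attribute `"peaks"` of simulator output); for curves without one,
#' `B_WIDE` blurs the curve with a Gaussian kernel and `B_NARROW` compresses
#' the channel axis towards the maximum. Shift anomalies translate the
#' channel series, padding with the edge value; a shift that would push the
#' curve maximum outside 1..200 is rejected.
#'
#' @param gc A [glow_curve].
#' @param spec An [anomaly_spec].
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @param config A [gc_config]; supplies the class-A windows and, for class
#'   E, the cascade the generate-and-filter loop checks against.
#' @return A [glow_curve] carrying the injected anomaly.
#' @export
inject_anomaly <- function(gc, spec, seed = NULL, config = gc_config()) {
  stopifnot(inherits(spec, "anomaly_spec"))
  if (!is_glow_curve(gc)) gc <- glow_curve(gc)
  if (!is.null(seed)) set.seed(seed)
  ch <- as.numeric(gc)
  mx <- max(ch)
  p <- spec$params
  out <- switch(spec$label,
    A_LOW = {
      w <- if (is.null(p$window)) c(config$BgdLTTLChLow, config$BgdLTTLChHigh)
           else p$window
      ch[w[1]:w[2]] <- ch[w[1]:w[2]] + p$pedestal * mx
      ch
    },
    A_HIGH = {
      w <- if (is.null(p$window)) c(config$BgdHTTLChLow, config$BgdHTTLChHigh)
           else p$window
      ch[w[1]:w[2]] <- ch[w[1]:w[2]] + p$pedestal * mx
      ch
    },
    B_WIDE = inject_wide(gc, p$width_scale),
    B_NARROW = inject_narrow(gc, p$width_scale),
    C_LOW = shift_curve(ch, -abs(p$shift)),
    C_HIGH = shift_curve(ch, abs(p$shift)),
    D = inject_spikes(ch, p$n_spikes, p$spike_factor),
    E = inject_ripple(ch, p$ripple_amp, p$ripple_period, config)
  )
  glow_curve(pmax(out, 0))
}

# Translate the channel series by `shift` channels, padding with edge values.
shift_curve <- function(ch, shift) {
  shift <- as.integer(round(shift))
  peak <- which.max(ch)
  if (peak + shift < 1L || peak + shift > GC_CHANNELS)
    stop("shift would push the curve maximum outside channels 1..200")
  x <- seq_len(GC_CHANNELS) - shift
  ch[pmin(pmax(x, 1L), GC_CHANNELS)]
}

inject_wide <- function(gc, scale) {
  peaks <- attr(gc, "peaks")
  if (!is.null(peaks)) {
    # widen the dominant (tallest) peak only: the dosimetric peak spreads
    # while the satellite structure stays put
    heights <- vapply(peaks, `[[`, numeric(1), "height")
    k <- which.max(heights)
    peaks[[k]]$width <- peaks[[k]]$width * scale
    return(gc_shape(peaks))
  }
  # fallback: Gaussian blur widening every feature, integral-preserving
  ch <- as.numeric(gc)
  sk <- max(sd_blur_kernel_sigma(scale), 1)
  half <- ceiling(3 * sk)
  kern <- stats::dnorm(-half:half, 0, sk)
  kern <- kern / sum(kern)
  padded <- c(rep(ch[1], half), ch, rep(ch[GC_CHANNELS], half))
  stats::filter(padded, kern, sides = 2)[(half + 1):(half + GC_CHANNELS)]
}

# kernel sigma giving roughly a `scale`-fold widening of the default main peak
sd_blur_kernel_sigma <- function(scale) sqrt(pmax(scale^2 - 1, 0)) * 8

inject_narrow <- function(gc, scale) {
  peaks <- attr(gc, "peaks")
  if (!is.null(peaks)) {
    peaks <- lapply(peaks, function(p) { p$width <- p$width * scale; p })
    return(gc_shape(peaks))
  }
  # fallback: compress the channel axis towards the maximum
  ch <- as.numeric(gc)
  peak <- which.max(ch)
  src <- peak + (seq_len(GC_CHANNELS) - peak) / scale
  out <- stats::approx(seq_len(GC_CHANNELS), ch, xout = src, rule = 1)$y
  out[is.na(out)] <- 0
  out
}

inject_spikes <- function(ch, n_spikes, factor) {
  mx <- max(ch)
  # spread spike sites across the informative channel range, at least four
  # channels apart so each spike is a separate event under the detector
  candidates <- seq(20L, 180L, by = 1L)
  sites <- integer(0)
  pool <- candidates
  for (k in seq_len(n_spikes)) {
    if (!length(pool)) break
    s <- pool[sample.int(length(pool), 1)]
    sites <- c(sites, s)
    pool <- pool[abs(pool - s) > 4L]
  }
  if (length(sites) < n_spikes)
    stop("could not place ", n_spikes, " spikes at least 4 channels apart")
  for (s in sort(sites)) {
    width <- sample(1:2, 1)
    idx <- s:min(s + width - 1L, GC_CHANNELS)
    ch[idx] <- factor * pmax(ch[idx], 0.05 * mx)
  }
  ch
}

inject_ripple <- function(ch, amp, period, config, max_tries = 100L) {
  # generate-and-filter: resample the ripple phase until the cascade assigns
  # exactly the residual class E
  for (try in seq_len(max_tries)) {
    phase <- stats::runif(1, 0, period)
    y <- ch * (1 + amp * sin(2 * pi * (seq_len(GC_CHANNELS) - phase) / period))
    y <- pmax(y, 0)
    out <- classify_gc(glow_curve(y), config)
    if (identical(out$labels, "E")) return(y)
  }
  stop("could not construct a class-E distortion in ", max_tries, " tries")
}

#' Generate a labeled synthetic dataset
#'
#' Draws `n_total` glow curves, of which `round(n_total * anomalous_fraction)`
#' carry an injected anomaly; the anomalous count is apportioned across the
#' eight labels by `class_mix` using largest-remainder rounding, so exact
#' class counts are reproducible from the seed. The default anomalous
#' fraction, 144/1608, mirrors the imbalance of the operational training set
#' this simulator stands in for.
#'
#' @param n_total Number of curves.
#' @param anomalous_fraction Fraction of curves carrying an anomaly, in
#'   `[0, 1]`.
#' @param class_mix Named or unnamed non-negative weights over the eight
#'   anomaly labels (recycled/normalized); default equal weights.
#' @param seed Integer seed driving every random draw.
#' @param noise_cv,shape_jitter Passed to [generate_normal_gc].
#' @param config Passed to [inject_anomaly].
#' @return A list of class `gc_dataset` with `curves` (list of
#'   [glow_curve]) and `labels` (character; `"NORMAL"` or an anomaly label).
#' @examples
#' ds <- generate_labeled_dataset(50, seed = 1)
#' table(ds$labels)
#' @export
generate_labeled_dataset <- function(n_total,
                                     anomalous_fraction = 144 / 1608,
                                     class_mix = NULL, seed = 1,
                                     noise_cv = 0.05, shape_jitter = 0.1,
                                     config = gc_config()) {
  stopifnot(n_total >= 0, anomalous_fraction >= 0, anomalous_fraction <= 1)
  if (n_total == 0)
    return(structure(list(curves = list(), labels = character()),
                     class = "gc_dataset"))
  if (is.null(class_mix)) class_mix <- rep(1, length(GC_LABELS))
  if (is.null(names(class_mix))) {
    stopifnot(length(class_mix) == length(GC_LABELS))
    names(class_mix) <- GC_LABELS
  }
  class_mix <- class_mix[GC_LABELS]
  class_mix[is.na(class_mix)] <- 0
  n_anom <- round(n_total * anomalous_fraction)
  counts <- apportion(n_anom, class_mix)
  labels <- c(rep("NORMAL", n_total - n_anom), rep(GC_LABELS, counts))

  set.seed(seed)
  curves <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    gc <- generate_normal_gc(seed = NULL, noise_cv = noise_cv,
                             shape_jitter = shape_jitter)
    if (labels[i] != "NORMAL")
      gc <- inject_anomaly(gc, anomaly_spec(labels[i]), seed = NULL,
                           config = config)
    curves[[i]] <- gc
  }
  structure(list(curves = curves, labels = labels), class = "gc_dataset")
}

# Largest-remainder apportionment of `n` items over non-negative weights.
apportion <- function(n, weights) {
  if (n == 0 || sum(weights) == 0)
    return(stats::setNames(integer(length(weights)), names(weights)))
  quota <- n * weights / sum(weights)
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(quota - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(counts), names(weights))
}

#' @export
print.gc_dataset <- function(x, ...) {
  cat("<gc_dataset>", length(x$curves), "curves\n")
  print(table(x$labels))
  invisible(x)
}

#' Simulate a batch of dosimeter records
#'
#' Builds full dosimeter records (4 elements with concordant doses, read
#' dates one month apart, per-element curves) for end-to-end pipeline runs.
#' A `below_reporting_fraction` of the batch gets near-zero doses; of the
#' remainder, `anomalous_fraction` carry one anomalous element curve with a
#' label drawn from `class_mix`.
#'
#' @param n Number of dosimeters.
#' @param anomalous_fraction Fraction of above-reporting dosimeters with an
#'   injected anomaly.
#' @param below_reporting_fraction Fraction of the batch with doses under the
#'   reporting level.
#' @param class_mix As in [generate_labeled_dataset].
#' @param seed Integer seed.
#' @param noise_cv,shape_jitter Passed to [generate_normal_gc].
#' @param config A [gc_config].
#' @return A list with `records` (list of [dosimeter_record]) and `labels`
#'   (character: `"BELOW"`, `"NORMAL"` or the injected anomaly label).
#' @export
simulate_dosimeter_batch <- function(n, anomalous_fraction = 0.1,
                                     below_reporting_fraction = 0.3,
                                     class_mix = NULL, seed = 1,
                                     noise_cv = 0.05, shape_jitter = 0.1,
                                     config = gc_config()) {
  if (is.null(class_mix)) class_mix <- rep(1, length(GC_LABELS))
  if (is.null(names(class_mix))) names(class_mix) <- GC_LABELS
  n_below <- round(n * below_reporting_fraction)
  n_anom <- round((n - n_below) * anomalous_fraction)
  counts <- apportion(n_anom, class_mix[GC_LABELS])
  labels <- c(rep("BELOW", n_below),
              rep("NORMAL", n - n_below - n_anom),
              rep(GC_LABELS, counts))
  set.seed(seed)
  labels <- sample(labels)
  read_date <- as.Date("2024-02-01")
  prev_date <- as.Date("2024-01-01")
  records <- vector("list", n)
  for (i in seq_len(n)) {
    base_dose <- if (labels[i] == "BELOW") stats::runif(1, 0, 7)
                 else stats::runif(1, 40, 200)
    doses <- base_dose * stats::runif(4, 0.92, 1.08)   # concordant elements
    curves <- lapply(1:4, function(j)
      generate_normal_gc(seed = NULL, noise_cv = noise_cv,
                         shape_jitter = shape_jitter))
    if (labels[i] %in% GC_LABELS)
      curves[[1]] <- inject_anomaly(curves[[1]], anomaly_spec(labels[i]),
                                    seed = NULL, config = config)
    records[[i]] <- dosimeter_record(
      dosimeter_id = sprintf("SIM%05d", i),
      reader_id = sprintf("RD%02d", 1 + (i %% 3)),
      curves = curves, element_doses = doses,
      read_date = read_date, prev_read_date = prev_date,
      ecc = round(stats::runif(4, 0.95, 1.05), 3)
    )
  }
  list(records = records, labels = labels)
}
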