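#' Pipeline configuration
#'
#' All tunable parameters of the QC pipeline, by the names used in the
#' reader-side configuration file. Values not supplied keep their defaults.
#'
#' Dose-side parameters (mrem): `ManualReviewThreshold` (above it a dosimeter
#' is always manually checked), `Threshold1..Threshold3`, `ThresholdNeut`,
#' `ThresholdRing` (element doses below these are zeroed before the
#' reporting-level test), `RadiationPerWeek` (weekly background accrual,
#' default 1 mrem/week), `reporting_level` (20 mrem) and `low_dose_cut`
#' (16 mrem: the largest post-background total that is still filtered out).
#'
#' Ratio filter: `Crystals_Quotient` (maximum allowed relative spread of the
#' element doses) and `ratio_table_threshold` (absolute tolerance when
#' matching dose ratios against the radiation-field table).
#'
#' Shape filter: `bUseAI`, `training_model_file`, `ai_probability_threshold`
#' (default 0.91; a curve is accepted as normal only when the network's
#' probability strictly exceeds it).
#'
#' Class A: `MinBgdHeight`/`MaxBgdHeight` (% of the curve maximum bounding an
#' elevated-background window average), `BgdLTTLChLow..BgdLTTLChHigh` and
#' `BgdHTTLChLow..BgdHTTLChHigh` (inclusive low/high-temperature windows),
#' `LowCutCh`/`HighCutCh` (cut boundaries used by the correction).
#'
#' Class B: `TLDWideLowCh..TLDWideHighCh` and `WideAvgVal` (%) for wide
#' curves; `half_width_num_ch` and `NarrowAvgVal` (%) for narrow ones.
#'
#' Class C: `MaxAllowedShift` (channels around channel 95).
#'
#' Class D: `NSpikes` (more than this many spikes classifies the curve) and
#' `SpikeNeighDiff` (% jump between neighbouring channels that counts as a
#' spike edge).
#'
#' Plumbing: `MDBPath` (input file path), `bFullAutomated` (apply class-A
#' corrections without technician approval), `dose_calibration` (mrem per
#' unit of curve integral), `random_seed`.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `gc_config`.
#' @examples
#' cfg <- gc_config(MaxAllowedShift = 8)
#' validate_config(cfg)
#' @export
gc_config <- function(...) {
  cfg <- list(
    ManualReviewThreshold   = 500,
    bFullAutomated          = FALSE,
    Threshold1              = 1,
    Threshold2              = 1,
    Threshold3              = 1,
    ThresholdNeut           = 1,
    ThresholdRing           = 1,
    RadiationPerWeek        = 1,
    Crystals_Quotient       = 0.25,
    ratio_table_threshold   = 0.05,
    MDBPath                 = "",
    bUseAI                  = TRUE,
    training_model_file     = "gc_filter_model.json",
    ai_probability_threshold = 0.91,
    MaxBgdHeight            = 50,
    MinBgdHeight            = 10,
    BgdHTTLChLow            = 160L,
    BgdHTTLChHigh           = 200L,
    BgdLTTLChLow            = 1L,
    BgdLTTLChHigh           = 40L,
    LowCutCh                = 40L,
    HighCutCh               = 160L,
    TLDWideLowCh            = 55L,
    TLDWideHighCh           = 135L,
    WideAvgVal              = 60,
    half_width_num_ch       = 25L,
    NarrowAvgVal            = 5,
    MaxAllowedShift         = 10L,
    NSpikes                 = 3L,
    SpikeNeighDiff          = 50,
    expected_peak_channel   = EXPECTED_PEAK_CHANNEL,
    reporting_level         = 20,
    low_dose_cut            = 16,
    dose_calibration        = 0.005,
    random_seed             = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown configuration parameter(s): ",
           paste(unknown, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  structure(cfg, class = "gc_config")
}

#' @export
print.gc_config <- function(x, ...) {
  cat("<gc_config> pipeline configuration,", length(x), "parameters\n")
  v <- validate_config(x)
  if (length(v)) cat("invalid:\n", paste(" -", v, collapse = "\n"), "\n")
  invisible(x)
}

#' Validate a pipeline configuration
#'
#' Checks every structural invariant of the configuration and reports
#' violations instead of raising, so a caller can surface all problems at
#' once. Each violation message names the offending parameter(s).
#'
#' @param config A [gc_config] object or plain named list.
#' @return Character vector of violations; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  v <- character()
  bad <- function(msg) v <<- c(v, msg)
  num1 <- function(name) {
    x <- config[[name]]
    is.numeric(x) && length(x) == 1 && is.finite(x)
  }
  for (name in c("BgdLTTLChLow", "BgdLTTLChHigh", "BgdHTTLChLow",
                 "BgdHTTLChHigh", "MinBgdHeight", "MaxBgdHeight",
                 "ai_probability_threshold", "MaxAllowedShift", "NSpikes",
                 "SpikeNeighDiff", "RadiationPerWeek", "Crystals_Quotient",
                 "ratio_table_threshold", "WideAvgVal", "NarrowAvgVal",
                 "half_width_num_ch", "TLDWideLowCh", "TLDWideHighCh",
                 "LowCutCh", "HighCutCh"))
    if (!num1(name)) bad(paste0(name, " must be a single finite number"))
  if (length(v)) return(v)

  with(config, {
    if (!(1 <= BgdLTTLChLow && BgdLTTLChLow <= BgdLTTLChHigh))
      bad("BgdLTTLChLow must satisfy 1 <= BgdLTTLChLow <= BgdLTTLChHigh")
    if (!(BgdLTTLChHigh < BgdHTTLChLow))
      bad("BgdLTTLChHigh must be below BgdHTTLChLow (windows must not overlap)")
    if (!(BgdHTTLChLow <= BgdHTTLChHigh && BgdHTTLChHigh <= GC_CHANNELS))
      bad("BgdHTTLChLow..BgdHTTLChHigh must be an interval inside 1..200")
    if (!(0 <= MinBgdHeight && MinBgdHeight < MaxBgdHeight))
      bad("MinBgdHeight must be >= 0 and below MaxBgdHeight")
    if (!(MaxBgdHeight <= 100))
      bad("MaxBgdHeight must be at most 100 (percent of curve maximum)")
    if (!(ai_probability_threshold > 0 && ai_probability_threshold < 1))
      bad("ai_probability_threshold must lie strictly between 0 and 1")
    if (MaxAllowedShift < 0) bad("MaxAllowedShift must be >= 0")
    if (NSpikes < 0) bad("NSpikes must be >= 0")
    if (SpikeNeighDiff <= 0) bad("SpikeNeighDiff must be > 0")
    if (RadiationPerWeek <= 0) bad("RadiationPerWeek must be > 0")
    if (!(Crystals_Quotient >= 0 && Crystals_Quotient <= 1))
      bad("Crystals_Quotient must lie in [0, 1]")
    if (!(ratio_table_threshold >= 0 && ratio_table_threshold <= 1))
      bad("ratio_table_threshold must lie in [0, 1]")
    if (!(1 <= TLDWideLowCh && TLDWideLowCh <= TLDWideHighCh &&
          TLDWideHighCh <= GC_CHANNELS))
      bad("TLDWideLowCh..TLDWideHighCh must be an interval inside 1..200")
    if (!(1 <= LowCutCh && LowCutCh <= GC_CHANNELS))
      bad("LowCutCh must be a channel index in 1..200")
    if (!(1 <= HighCutCh && HighCutCh <= GC_CHANNELS))
      bad("HighCutCh must be a channel index in 1..200")
    if (half_width_num_ch < 1)
      bad("half_width_num_ch must be at least 1 channel")
  })
  v
}

#' Read or write a configuration file
#'
#' Configurations are stored as YAML keyed by the parameter names of
#' [gc_config]; unknown keys are rejected so typos do not silently fall back
#' to defaults.
#'
#' @param path File path.
#' @return `read_config` returns a [gc_config]; `write_config` returns `path`
#'   invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(gc_config, raw)
}

#' @param config A [gc_config].
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
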