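#' Open (or create) a per-dosimeter statistics store
#'
#' The store is a single append-only CSV file holding one row per processed
#' dosimeter per run: curve statistics (min/max/median per element), element
#' correction coefficients and responses, every filter decision, the
#' shape-filter probability, assigned classes, correction fields and
#' timestamps. Rows are only ever appended, never rewritten.
#'
#' @param path CSV file path; created on first write.
#' @return An object of class `gc_stats_store`.
#' @export
stats_store <- function(path) {
  structure(list(path = path), class = "gc_stats_store")
}

#' @export
print.gc_stats_store <- function(x, ...) {
  n <- if (file.exists(x$path)) nrow(read_stats(x)) else 0L
  cat("<gc_stats_store>", x$path, "-", n, "record(s)\n")
  invisible(x)
}

stat_columns <- function() {
  c("stored_id", "dosimeter_id", "reader_id", "read_date", "prev_read_date",
    "timestamp", "bgd_mrem", "total_dose_mrem", "stage_reached", "labels",
    "ai_probability", "spike_count", "corrected", "correction_delta_mrem",
    "beam", "ecc", "responses", "gc_min", "gc_max", "gc_median",
    "element_doses_raw", "element_doses")
}

join_num <- function(x) paste(format(x, digits = 10, trim = TRUE),
                              collapse = ";")

#' Persist one dosimeter's QC statistics
#'
#' Appends a [stat row][stats_store] assembled from a pipeline outcome and
#' its record. Storage failures abort with a clear message (a silent loss of
#' audit rows is worse than a stopped run).
#'
#' @param outcome A `gc_outcome` as produced by [run_pipeline] (or built
#'   with the same fields).
#' @param record The corresponding [dosimeter_record] (background-subtracted).
#' @param store A `gc_stats_store`.
#' @return The stored id (character), invisibly.
#' @export
record_statistics <- function(outcome, record, store) {
  stopifnot(inherits(store, "gc_stats_store"))
  mins <- vapply(record$curves, function(g) min(as.numeric(g)), numeric(1))
  maxs <- vapply(record$curves, function(g) max(as.numeric(g)), numeric(1))
  meds <- vapply(record$curves, function(g) stats::median(as.numeric(g)),
                 numeric(1))
  raw <- if (is.null(record$raw_element_doses)) record$element_doses
         else record$raw_element_doses
  stored_id <- paste0(record$dosimeter_id, "@",
                      format(record$read_date, "%Y-%m-%d"))
  row <- data.frame(
    stored_id = stored_id,
    dosimeter_id = record$dosimeter_id,
    reader_id = record$reader_id,
    read_date = format(record$read_date, "%Y-%m-%d"),
    prev_read_date = if (is.na(record$prev_read_date)) ""
                     else format(record$prev_read_date, "%Y-%m-%d"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
    bgd_mrem = if (is.null(record$bgd)) NA_real_ else record$bgd,
    total_dose_mrem = outcome$total_dose,
    stage_reached = outcome$stage_reached,
    labels = paste(outcome$labels, collapse = "|"),
    ai_probability = if (is.null(outcome$ai_probability)) NA_real_
                     else outcome$ai_probability,
    spike_count = if (is.null(outcome$spike_count)) NA_integer_
                  else outcome$spike_count,
    corrected = isTRUE(outcome$corrected),
    correction_delta_mrem = if (is.null(outcome$correction_delta)) NA_real_
                            else outcome$correction_delta,
    beam = if (is.null(outcome$beam) || is.na(outcome$beam)) ""
           else outcome$beam,
    ecc = join_num(record$ecc),
    responses = join_num(record$element_doses / record$ecc),
    gc_min = join_num(mins),
    gc_max = join_num(maxs),
    gc_median = join_num(meds),
    element_doses_raw = join_num(raw),
    element_doses = join_num(record$element_doses),
    stringsAsFactors = FALSE
  )
  new <- !file.exists(store$path)
  ok <- tryCatch({
    utils::write.table(row, store$path, append = !new, col.names = new,
                       row.names = FALSE, sep = ",", qmethod = "double")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("failed to persist statistics for ", record$dosimeter_id, " to ",
         store$path, ": ", conditionMessage(ok))
  invisible(stored_id)
}

#' Read back the statistics store
#'
#' @param store A `gc_stats_store`.
#' @return Data frame of all stored rows (zero rows when the store is empty).
#' @export
read_stats <- function(store) {
  if (!file.exists(store$path)) {
    empty <- as.data.frame(stats::setNames(
      replicate(length(stat_columns()), character(0), simplify = FALSE),
      stat_columns()), stringsAsFactors = FALSE)
    return(empty)
  }
  utils::read.csv(store$path, stringsAsFactors = FALSE,
                  colClasses = c(dosimeter_id = "character",
                                 reader_id = "character",
                                 labels = "character", beam = "character"))
}

#' Query stored statistics
#'
#' @param store A `gc_stats_store`.
#' @param from,to Optional read-date range (inclusive).
#' @param reader Optional reader id.
#' @param label Optional anomaly label; matches rows whose label set
#'   contains it.
#' @return Data frame of matching rows.
#' @export
query_stats <- function(store, from = NULL, to = NULL, reader = NULL,
                        label = NULL) {
  df <- read_stats(store)
  if (!nrow(df)) return(df)
  keep <- rep(TRUE, nrow(df))
  dates <- as.Date(df$read_date)
  if (!is.null(from)) keep <- keep & dates >= as.Date(from)
  if (!is.null(to)) keep <- keep & dates <= as.Date(to)
  if (!is.null(reader)) keep <- keep & df$reader_id == reader
  if (!is.null(label))
    keep <- keep & vapply(strsplit(df$labels, "|", fixed = TRUE),
                          function(l) label %in% l, logical(1))
  df[keep, , drop = FALSE]
}

#' Class-distribution summary of a statistics store
#'
#' Counts dosimeters per terminal stage and per anomaly label. The two
#' class-A sub-classes are counted per label, so a dosimeter classified to
#' both `A_LOW` and `A_HIGH` contributes to both counts and the label counts
#' may exceed the number of classified dosimeters.
#'
#' @inheritParams query_stats
#' @return Data frame with columns `category` and `count`; zero rows for an
#'   empty query.
#' @export
summarize_distribution <- function(store, from = NULL, to = NULL,
                                   reader = NULL) {
  df <- query_stats(store, from = from, to = to, reader = reader)
  if (!nrow(df))
    return(data.frame(category = character(), count = integer(),
                      stringsAsFactors = FALSE))
  cats <- c("below_reporting", "ai_normal", "manual_review_ratio_fail")
  counts <- vapply(cats, function(s) sum(df$stage_reached == s), integer(1))
  all_labels <- unlist(strsplit(df$labels[df$stage_reached == "classified"],
                                "|", fixed = TRUE))
  lab_counts <- vapply(GC_LABELS, function(l) sum(all_labels == l),
                       integer(1))
  out <- data.frame(
    category = c(cats, GC_LABELS),
    count = as.integer(c(counts, lab_counts)),
    stringsAsFactors = FALSE
  )
  out[out$count > 0 | out$category %in% cats, , drop = FALSE]
}

# priority used to pick the dosimeter-level label set from its elements
label_priority <- function(labels) {
  if ("D" %in% labels) return(4L)
  if (any(c("A_LOW", "A_HIGH") %in% labels)) return(3L)
  if (any(c("C_LOW", "C_HIGH") %in% labels)) return(2L)
  if (any(c("B_WIDE", "B_NARROW") %in% labels)) return(1L)
  0L  # E
}

#' Run the full glow-curve QC pipeline
#'
#' Executes the stages in order — background reduction, low-dose filter,
#' shape (AI) filter, integral-ratio filter, spike classification,
#' smoothing, the A/C/B/E cascade, class-A correction, statistics — over a
#' batch of dosimeter records. Every dosimeter reaches exactly one terminal
#' disposition: `quarantined` (malformed input), `below_reporting`,
#' `ai_normal`, `manual_review_ratio_fail` or `classified`.
#'
#' Element curves are classified individually; the dosimeter-level label set
#' is taken from its highest-priority anomalous element (spikes, then
#' elevated background, then shift, then width, then the residual class).
#'
#' @param input A list of [dosimeter_record] objects, a list as returned by
#'   [read_gc_csv], or a path to a record CSV.
#' @param config A [gc_config] or path to a YAML configuration file.
#' @param model A `gc_filter`, a path to a persisted model, or `NULL`.
#'   With `NULL` (or `bUseAI = FALSE`) the shape filter is bypassed and all
#'   retained curves go to the rule cascade.
#' @param stats_path Path for the statistics store; defaults to a file in
#'   `tempdir()`.
#' @param out Optional CSV path for the per-dosimeter outcome table.
#' @return An object of class `gc_pipeline_result`: `outcomes` (list of
#'   `gc_outcome`), `table` (data frame, one row per non-quarantined
#'   dosimeter), `store`, `summary` (named disposition counts),
#'   `quarantined`, and `stage_log` (one entry per stage with in/out
#'   counts).
#' @export
run_pipeline <- function(input, config = gc_config(), model = NULL,
                         stats_path = file.path(tempdir(), "glowqc_stats.csv"),
                         out = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (is.character(model)) model <- read_filter_model(model)
  if (is.character(input)) input <- read_gc_csv(input)
  if (is.list(input) && !is.null(input$records)) {
    records <- input$records
    quarantined <- input$quarantined
  } else {
    records <- input
    quarantined <- data.frame(dosimeter_id = character(),
                              error = character(), stringsAsFactors = FALSE)
  }
  store <- stats_store(stats_path)
  rtab <- ratio_table()
  use_ai <- isTRUE(config$bUseAI) && !is.null(model)

  outcomes <- vector("list", length(records))
  n_in <- length(records)
  counts <- c(below_reporting = 0L, ai_normal = 0L,
              manual_review_ratio_fail = 0L, classified = 0L)

  for (i in seq_along(records)) {
    rec <- records[[i]]
    bg <- compute_background(rec$prev_read_date, rec$read_date,
                             config$RadiationPerWeek)
    rec <- subtract_background(rec, bg)
    outcome <- list(dosimeter_id = rec$dosimeter_id, labels = character(),
                    ai_probability = NA_real_, spike_count = NA_integer_,
                    corrected = FALSE, correction_delta = NA_real_,
                    beam = NA_character_)

    ldf <- low_dose_filter(rec, config)
    outcome$total_dose <- ldf$total_dose
    if (ldf$decision == "filtered_out") {
      outcome$stage_reached <- "below_reporting"
    } else {
      suspected <- rep(TRUE, n_elements(rec))
      if (use_ai) {
        probs <- vapply(rec$curves, function(g)
          classify_normal(g, model, config$ai_probability_threshold)$probability,
          numeric(1))
        outcome$ai_probability <- min(probs)
        suspected <- probs <= config$ai_probability_threshold
      }
      if (use_ai && !any(suspected)) {
        outcome$stage_reached <- "ai_normal"
      } else {
        pf <- prefilter_dosimeter(rec, config, rtab)
        outcome$beam <- pf$beam
        if (pf$decision == "manual_review") {
          outcome$stage_reached <- "manual_review_ratio_fail"
        } else {
          outcome$stage_reached <- "classified"
          elt <- which(suspected)
          cls <- lapply(rec$curves[elt], classify_gc, config = config)
          pri <- vapply(cls, function(x) label_priority(x$labels), integer(1))
          best <- which.max(pri)
          chosen <- cls[[best]]
          outcome$labels <- chosen$labels
          outcome$spike_count <- chosen$spike_report$count
          if (all(outcome$labels %in% c("A_LOW", "A_HIGH"))) {
            corr <- correct_class_a(rec$curves[[elt[best]]], outcome$labels,
                                    config, rec$dosimeter_id)
            prop <- apply_or_suggest(corr$proposal, config$bFullAutomated,
                                     config)
            outcome$corrected <- identical(prop$status, "applied")
            outcome$correction_delta <- prop$dose_before - prop$dose_after
            outcome$correction <- prop
            if (outcome$corrected)
              rec$curves[[elt[best]]] <- corr$curve
          }
        }
      }
    }
    counts[outcome$stage_reached] <- counts[outcome$stage_reached] + 1L
    class(outcome) <- "gc_outcome"
    outcome$stored_id <- record_statistics(outcome, rec, store)
    outcomes[[i]] <- outcome
  }

  stage_log <- list(
    list(stage = "input", n_in = n_in + nrow(quarantined),
         quarantined = nrow(quarantined), n_out = n_in),
    list(stage = "low_dose_filter", n_in = n_in,
         filtered_out = unname(counts["below_reporting"]),
         n_out = n_in - unname(counts["below_reporting"])),
    list(stage = "ai_filter",
         n_in = n_in - unname(counts["below_reporting"]),
         filtered_out = unname(counts["ai_normal"]),
         n_out = n_in - unname(counts["below_reporting"]) -
           unname(counts["ai_normal"])),
    list(stage = "ratio_filter",
         n_in = n_in - unname(counts["below_reporting"]) -
           unname(counts["ai_normal"]),
         manual_review = unname(counts["manual_review_ratio_fail"]),
         n_out = unname(counts["classified"])),
    list(stage = "classifier", n_in = unname(counts["classified"]),
         n_out = unname(counts["classified"]))
  )

  df <- do.call(rbind, lapply(outcomes, function(o) data.frame(
    dosimeter_id = o$dosimeter_id,
    stage_reached = o$stage_reached,
    labels = paste(o$labels, collapse = "|"),
    ai_probability = o$ai_probability,
    spike_count = o$spike_count,
    total_dose_mrem = o$total_dose,
    corrected = o$corrected,
    correction_delta_mrem = o$correction_delta,
    stringsAsFactors = FALSE
  )))
  if (is.null(df))
    df <- data.frame(dosimeter_id = character(), stage_reached = character(),
                     labels = character(), ai_probability = numeric(),
                     spike_count = integer(), total_dose_mrem = numeric(),
                     corrected = logical(), correction_delta_mrem = numeric(),
                     stringsAsFactors = FALSE)
  if (!is.null(out)) utils::write.csv(df, out, row.names = FALSE)

  structure(list(
    outcomes = outcomes,
    table = df,
    store = store,
    summary = c(counts, quarantined = nrow(quarantined)),
    quarantined = quarantined,
    stage_log = stage_log
  ), class = "gc_pipeline_result")
}

#' @export
print.gc_pipeline_result <- function(x, ...) {
  cat("<gc_pipeline_result>\n")
  for (nm in names(x$summary))
    cat(sprintf("  %-26s %d\n", nm, x$summary[[nm]]))
  invisible(x)
}

#' @export
summary.gc_pipeline_result <- function(object, ...) {
  summarize_distribution(object$store)
}

#' One JSON line per pipeline stage, for scriptable funnels
#'
#' @param result A `gc_pipeline_result`.
#' @param con Connection or file path to write to; default standard output.
#' @return The JSON lines, invisibly.
#' @export
write_stage_log <- function(result, con = stdout()) {
  lines <- vapply(result$stage_log, function(entry)
    as.character(jsonlite::toJSON(entry, auto_unbox = TRUE)), character(1))
  writeLines(lines, con)
  invisible(lines)
}
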