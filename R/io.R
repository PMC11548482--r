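# Glow-curve record files: one row per element, 207 fixed columns
# dosimeter_id,reader_id,element,read_date,prev_read_date,dose_mrem,ecc,
# ch001..ch200 (+ optional `label`); dates ISO-8601. A JSON-lines dialect
# carries the same field names.

gc_csv_columns <- function() {
  c("dosimeter_id", "reader_id", "element", "read_date", "prev_read_date",
    "dose_mrem", "ecc", sprintf("ch%03d", seq_len(GC_CHANNELS)))
}

records_to_frame <- function(records, labels = NULL) {
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    n <- n_elements(r)
    chans <- do.call(rbind, lapply(r$curves, as.numeric))
    colnames(chans) <- sprintf("ch%03d", seq_len(GC_CHANNELS))
    df <- data.frame(
      dosimeter_id = r$dosimeter_id,
      reader_id = r$reader_id,
      element = seq_len(n),
      read_date = format(r$read_date, "%Y-%m-%d"),
      prev_read_date = if (is.na(r$prev_read_date)) ""
                       else format(r$prev_read_date, "%Y-%m-%d"),
      dose_mrem = r$element_doses,
      ecc = r$ecc,
      stringsAsFactors = FALSE
    )
    df <- cbind(df, as.data.frame(chans))
    if (!is.null(labels)) df$label <- labels[i]
    df
  })
  do.call(rbind, rows)
}

#' Write or read dosimeter records as CSV
#'
#' One row per crystal element; the 200 channel intensities occupy columns
#' `ch001..ch200`. An optional `label` column (written when `labels` is
#' supplied, e.g. for simulator output) survives the round trip.
#'
#' @param records List of [dosimeter_record] objects.
#' @param path File path.
#' @param labels Optional per-dosimeter label vector to store alongside.
#' @return `write_gc_csv` returns `path` invisibly. `read_gc_csv` returns a
#'   list with `records`, `labels` (or `NULL`), and `quarantined` (a data
#'   frame of dosimeter ids that failed to parse, with the error message).
#' @export
write_gc_csv <- function(records, path, labels = NULL) {
  utils::write.csv(records_to_frame(records, labels), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gc_csv
#' @export
read_gc_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(dosimeter_id = "character",
                                       reader_id = "character"))
  frame_to_records(df)
}

frame_to_records <- function(df) {
  need <- gc_csv_columns()
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("input is missing column(s): ", paste(missing, collapse = ", "))
  has_label <- "label" %in% names(df)
  ch_cols <- sprintf("ch%03d", seq_len(GC_CHANNELS))
  records <- list()
  labels <- character()
  quarantined <- data.frame(dosimeter_id = character(), error = character(),
                            stringsAsFactors = FALSE)
  for (id in unique(df$dosimeter_id)) {
    rows <- df[df$dosimeter_id == id, , drop = FALSE]
    rows <- rows[order(rows$element), , drop = FALSE]
    rec <- tryCatch({
      curves <- lapply(seq_len(nrow(rows)), function(i)
        glow_curve(as.numeric(rows[i, ch_cols])))
      prev <- rows$prev_read_date[1]
      dosimeter_record(
        dosimeter_id = id,
        reader_id = rows$reader_id[1],
        curves = curves,
        element_doses = rows$dose_mrem,
        read_date = rows$read_date[1],
        prev_read_date = if (is.na(prev) || !nzchar(prev)) NA else prev,
        ecc = rows$ecc
      )
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      quarantined <- rbind(quarantined,
                           data.frame(dosimeter_id = id,
                                      error = conditionMessage(rec),
                                      stringsAsFactors = FALSE))
    } else {
      records[[length(records) + 1L]] <- rec
      if (has_label) labels <- c(labels, rows$label[1])
    }
  }
  list(records = records,
       labels = if (has_label) labels else NULL,
       quarantined = quarantined)
}

#' Write or read dosimeter records as JSON lines
#'
#' One JSON object per element row, with the same field names as the CSV
#' dialect (`channels` holds the 200 intensities as an array).
#'
#' @inheritParams write_gc_csv
#' @return `write_gc_jsonl` returns `path` invisibly; `read_gc_jsonl`
#'   returns the same structure as [read_gc_csv].
#' @export
write_gc_jsonl <- function(records, path, labels = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    r <- records[[i]]
    for (e in seq_len(n_elements(r))) {
      obj <- list(
        dosimeter_id = r$dosimeter_id,
        reader_id = r$reader_id,
        element = e,
        read_date = format(r$read_date, "%Y-%m-%d"),
        prev_read_date = if (is.na(r$prev_read_date)) NA
                         else format(r$prev_read_date, "%Y-%m-%d"),
        dose_mrem = r$element_doses[e],
        ecc = r$ecc[e],
        channels = as.numeric(r$curves[[e]])
      )
      if (!is.null(labels)) obj$label <- labels[i]
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                                  null = "null", na = "null"), con)
    }
  }
  invisible(path)
}

#' @rdname write_gc_jsonl
#' @export
read_gc_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  objs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  ch <- do.call(rbind, lapply(objs, `[[`, "channels"))
  colnames(ch) <- sprintf("ch%03d", seq_len(GC_CHANNELS))
  pick <- function(field, default = NA) {
    vapply(objs, function(o) {
      v <- o[[field]]
      if (is.null(v)) default else v
    }, default)
  }
  df <- data.frame(
    dosimeter_id = pick("dosimeter_id", NA_character_),
    reader_id = pick("reader_id", NA_character_),
    element = pick("element", NA_real_),
    read_date = pick("read_date", NA_character_),
    prev_read_date = pick("prev_read_date", NA_character_),
    dose_mrem = pick("dose_mrem", NA_real_),
    ecc = pick("ecc", NA_real_),
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(ch))
  if (!is.null(objs[[1]]$label)) df$label <- pick("label", NA_character_)
  frame_to_records(df)
}

#' Read a labeled training dataset from CSV
#'
#' Interprets each row of the record CSV dialect (with a `label` column) as
#' one labeled curve, for feeding [train_filter].
#'
#' @param path CSV path as written by [write_gc_csv] with labels.
#' @return A `gc_dataset` (one curve per row; dosimeter structure ignored).
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) stop("dataset CSV needs a `label` column")
  ch_cols <- sprintf("ch%03d", seq_len(GC_CHANNELS))
  if (!all(ch_cols %in% names(df)))
    stop("dataset CSV needs channel columns ch001..ch200")
  curves <- lapply(seq_len(nrow(df)), function(i)
    glow_curve(as.numeric(df[i, ch_cols])))
  structure(list(curves = curves, labels = df$label), class = "gc_dataset")
}

#' Write a labeled dataset to CSV
#'
#' @param dataset A `gc_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  ch <- do.call(rbind, lapply(dataset$curves, as.numeric))
  colnames(ch) <- sprintf("ch%03d", seq_len(GC_CHANNELS))
  n <- length(dataset$curves)
  df <- data.frame(
    dosimeter_id = sprintf("GC%05d", seq_len(n)),
    reader_id = "SIM",
    element = 1L,
    read_date = "2024-02-01",
    prev_read_date = "2024-01-01",
    dose_mrem = vapply(dataset$curves, function(g) sum(as.numeric(g)),
                       numeric(1)),
    ecc = 1,
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(ch))
  df$label <- dataset$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
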