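outcome_stub <- function(id = "T001", stage = "classified",
                         labels = character(), total = 50,
                         prob = NA_real_, spikes = 0L) {
  structure(list(dosimeter_id = id, stage_reached = stage, labels = labels,
                 total_dose = total, ai_probability = prob,
                 spike_count = spikes, corrected = FALSE,
                 correction_delta = NA_real_, beam = NA_character_),
            class = "gc_outcome")
}

test_that("statistics rows carry curve stats, responses and filter outcomes", {
  store <- stats_store(withr::local_tempfile(fileext = ".csv"))
  rec <- subtract_background(make_record(), 2)
  id <- record_statistics(outcome_stub(labels = c("A_LOW", "A_HIGH")),
                          rec, store)
  df <- read_stats(store)
  expect_identical(nrow(df), 1L)
  expect_identical(df$stored_id, id)
  expect_identical(df$labels, "A_LOW|A_HIGH")
  mins <- as.numeric(strsplit(df$gc_min, ";")[[1]])
  meds <- as.numeric(strsplit(df$gc_median, ";")[[1]])
  expect_length(mins, 4)
  expect_equal(meds[1], median(as.numeric(rec$curves[[1]])),
               tolerance = 1e-6)
  expect_equal(df$bgd_mrem, 2)
  # appending keeps earlier rows intact
  record_statistics(outcome_stub(id = "T002", stage = "below_reporting",
                                 total = 3), rec, store)
  expect_identical(nrow(read_stats(store)), 2L)
})

test_that("queries filter by date range, reader and label", {
  store <- stats_store(withr::local_tempfile(fileext = ".csv"))
  r1 <- make_record(id = "Q1", read = "2024-01-15")
  r2 <- make_record(id = "Q2", read = "2024-03-15")
  record_statistics(outcome_stub("Q1", labels = "D"), r1, store)
  record_statistics(outcome_stub("Q2", labels = "A_LOW"), r2, store)
  expect_identical(query_stats(store, to = "2024-02-01")$dosimeter_id, "Q1")
  expect_identical(query_stats(store, label = "A_LOW")$dosimeter_id, "Q2")
  expect_identical(nrow(query_stats(store, reader = "RD99")), 0L)
})

test_that("distribution summary counts each class-A sub-label separately", {
  store <- stats_store(withr::local_tempfile(fileext = ".csv"))
  rec <- make_record()
  for (i in 1:3)
    record_statistics(outcome_stub(paste0("DUAL", i),
                                   labels = c("A_LOW", "A_HIGH")), rec, store)
  record_statistics(outcome_stub("SINGLE", labels = "A_LOW"), rec, store)
  record_statistics(outcome_stub("LOWD", stage = "below_reporting",
                                 labels = character()), rec, store)
  s <- summarize_distribution(store)
  cnt <- function(cat) s$count[s$category == cat]
  expect_identical(cnt("A_LOW"), 4L)
  expect_identical(cnt("A_HIGH"), 3L)
  # 4 dosimeters are in class A but the label counts sum to 7
  expect_identical(cnt("A_LOW") + cnt("A_HIGH"), 4L + 3L)
  expect_identical(cnt("below_reporting"), 1L)
})

test_that("an empty store summarizes to an empty table, not an error", {
  store <- stats_store(withr::local_tempfile(fileext = ".csv"))
  expect_identical(nrow(summarize_distribution(store)), 0L)
  expect_identical(nrow(query_stats(store)), 0L)
})

test_that("the pipeline conserves dosimeters across dispositions", {
  batch <- simulate_dosimeter_batch(40, anomalous_fraction = 0.3, seed = 3)
  res <- run_pipeline(batch$records,
                      stats_path = withr::local_tempfile(fileext = ".csv"))
  expect_identical(sum(res$summary), 40L)
  expect_identical(nrow(res$table), 40L)
  expect_identical(sort(res$table$dosimeter_id),
                   sort(vapply(batch$records, `[[`, "", "dosimeter_id")))
})

test_that("an end-to-end run recovers the injected batch composition", {
  cfg <- gc_config(bFullAutomated = TRUE)
  batch <- simulate_dosimeter_batch(60, anomalous_fraction = 0.5,
                                    below_reporting_fraction = 0.25, seed = 5,
                                    noise_cv = 0, config = cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_gc_csv(batch$records, csv, labels = batch$labels)
  res <- run_pipeline(csv, config = cfg, model = NULL,
                      stats_path = withr::local_tempfile(fileext = ".csv"))
  tb <- res$table
  lab_of <- function(id) batch$labels[match(id, vapply(batch$records, `[[`,
                                                       "", "dosimeter_id"))]
  expect_identical(unname(res$summary[["below_reporting"]]),
                   sum(batch$labels == "BELOW"))
  classified <- tb[tb$stage_reached == "classified", ]
  inj <- lab_of(classified$dosimeter_id)
  hit <- mapply(function(injected, got)
    injected %in% strsplit(got, "|", fixed = TRUE)[[1]] ||
      (injected == "NORMAL" && got == "E"),
    inj, classified$labels)
  expect_gte(mean(hit), 0.95)
  # class-A dosimeters were auto-corrected under bFullAutomated
  a_rows <- classified[grepl("^A", classified$labels), ]
  if (nrow(a_rows)) expect_true(all(a_rows$corrected))
})

test_that("empty input produces empty outputs and a bypassed AI stage reports zero filtered", {
  res <- run_pipeline(list(),
                      stats_path = withr::local_tempfile(fileext = ".csv"))
  expect_identical(nrow(res$table), 0L)
  expect_identical(sum(res$summary), 0L)

  batch <- simulate_dosimeter_batch(12, anomalous_fraction = 0,
                                    below_reporting_fraction = 0, seed = 6)
  small <- generate_labeled_dataset(200, anomalous_fraction = 0.2, seed = 2)
  model <- train_filter(small, seed = 1, epochs = 120)
  with_ai <- run_pipeline(batch$records, config = gc_config(), model = model,
                          stats_path = withr::local_tempfile(fileext = ".csv"))
  no_ai <- run_pipeline(batch$records, config = gc_config(bUseAI = FALSE),
                        model = model,
                        stats_path = withr::local_tempfile(fileext = ".csv"))
  expect_identical(unname(no_ai$summary[["ai_normal"]]), 0L)
  expect_gte(unname(with_ai$summary[["ai_normal"]]),
             unname(no_ai$summary[["ai_normal"]]))
  expect_gte(unname(no_ai$summary[["classified"]]),
             unname(with_ai$summary[["classified"]]))
})

test_that("re-running the same input yields identical outcomes apart from timestamps", {
  batch <- simulate_dosimeter_batch(15, anomalous_fraction = 0.4, seed = 9)
  r1 <- run_pipeline(batch$records,
                     stats_path = withr::local_tempfile(fileext = ".csv"))
  r2 <- run_pipeline(batch$records,
                     stats_path = withr::local_tempfile(fileext = ".csv"))
  expect_identical(r1$table, r2$table)
  s1 <- read_stats(r1$store); s2 <- read_stats(r2$store)
  drop_ts <- function(d) d[setdiff(names(d), "timestamp")]
  expect_identical(drop_ts(s1), drop_ts(s2))
})

test_that("stage logs are valid JSON lines covering every stage", {
  batch <- simulate_dosimeter_batch(10, seed = 2)
  res <- run_pipeline(batch$records,
                      stats_path = withr::local_tempfile(fileext = ".csv"))
  lines <- write_stage_log(res, withr::local_tempfile(fileext = ".jsonl"))
  expect_length(lines, 5)
  parsed <- lapply(lines, jsonlite::fromJSON)
  expect_identical(vapply(parsed, `[[`, "", "stage"),
                   c("input", "low_dose_filter", "ai_filter", "ratio_filter",
                     "classifier"))
})
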