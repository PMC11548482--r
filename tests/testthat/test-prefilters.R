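test_that("background accrues linearly in elapsed weeks with a 1 mrem floor", {
  d0 <- as.Date("2024-01-01")
  expect_equal(compute_background(d0, d0 + 7)$bgd, 1)
  expect_equal(compute_background(d0, d0 + 14)$bgd, 2)
  expect_equal(compute_background(d0, d0 + 35, radiation_per_week = 2)$bgd, 10)
  # negative elapsed time floors to 1
  expect_equal(compute_background(d0, d0 - 3)$bgd, 1)
  expect_equal(compute_background(d0, d0 - 3)$elapsed_days, -3)
  expect_warning(bg <- compute_background(NA, d0), "missing")
  expect_equal(bg$bgd, 1)
})

test_that("background never drops below 1 mrem for any date pair", {
  d0 <- as.Date("2024-01-01")
  set.seed(1)
  for (off in sample(-400:400, 60))
    expect_gte(compute_background(d0, d0 + off)$bgd, 1)
})

test_that("background subtraction reduces each element, floored at zero, keeping the originals", {
  r <- make_record(doses = c(30, 30, 30, 30))
  out <- subtract_background(r, compute_background(r$prev_read_date - 7,
                                                   r$prev_read_date + 7))
  expect_equal(out$element_doses, c(28, 28, 28, 28))
  expect_equal(out$raw_element_doses, c(30, 30, 30, 30))
  low <- subtract_background(make_record(doses = c(1, 30, 30, 30)), 2)
  expect_equal(low$element_doses[1], 0)
})

test_that("low-dose filter cuts at 16 mrem with per-element thresholding first", {
  cfg <- gc_config()
  filt <- function(doses) low_dose_filter(make_record(doses = doses), cfg)
  expect_identical(filt(c(16, 0, 0, 0))$decision, "filtered_out")
  expect_identical(filt(c(17, 0, 0, 0))$decision, "retained")
  expect_identical(filt(c(0, 0, 0, 0))$decision, "filtered_out")
  # sub-threshold elements are zeroed before the total test
  custom <- gc_config(Threshold1 = 5, Threshold2 = 5, Threshold3 = 5,
                      ThresholdNeut = 5)
  out <- low_dose_filter(make_record(doses = c(4, 4, 4, 8)), custom)
  expect_identical(out$decision, "filtered_out")
  expect_equal(out$total_dose, 8)
  expect_identical(out$zeroed_elements, 1:3)
})

test_that("crystal spread check is scale- and permutation-invariant", {
  expect_true(crystal_spread_check(c(10, 10, 10, 10), 0.25))
  expect_false(crystal_spread_check(c(10, 10, 10, 5), 0.25))  # spread 0.5
  set.seed(4)
  for (i in 1:25) {
    doses <- stats::runif(4, 1, 100)
    q <- stats::runif(1, 0.05, 0.95)
    base <- crystal_spread_check(doses, q)
    expect_identical(crystal_spread_check(sample(doses), q), base)
    expect_identical(crystal_spread_check(doses * 1000, q), base)
  }
  expect_false(crystal_spread_check(c(0, 0, 0), 0.5))  # divide-by-zero guard
})

test_that("equal doses match the unit-ratio reference field", {
  m <- ratio_table_match(c(1, 1, 1, 1), tol = 0.05)
  expect_true("Cs137" %in% m$matches)
  expect_false(is.na(m$beam))
})

test_that("doses built by inverting the NS60 row match it at tight tolerance", {
  m <- ratio_table_match(c(1.000, 1.011, 1.042, 1.000), tol = 0.02)
  expect_identical(m$beam, "NS60")
  expect_identical(oracle_ratio_match(c(1.000, 1.011, 1.042, 1.000),
                                      ratio_table(), 0.02), "NS60")
})

test_that("wildly discordant doses match no field", {
  m <- ratio_table_match(c(1, 100, 1, 1), tol = 0.01)
  expect_true(is.na(m$beam))
  expect_length(oracle_ratio_match(c(1, 100, 1, 1), ratio_table(), 0.01), 0)
})

test_that("ratio matching agrees with the exhaustive row scan on random quadruples and triplets", {
  tab <- ratio_table()
  set.seed(11)
  for (i in 1:300) {
    n <- sample(3:4, 1)
    doses <- round(stats::runif(n, 0, 20), 2)
    if (max(doses) == 0) next
    tol <- sample(c(0.02, 0.05, 0.1), 1)
    got <- ratio_table_match(doses, tab, tol)
    want <- oracle_ratio_match(doses, tab, tol)
    expect_identical(got$matches, want,
                     label = paste("doses", paste(doses, collapse = ",")))
  }
})

test_that("prefilter passes on spread OR table match and fails to manual review otherwise", {
  cfg <- gc_config()
  # concordant doses: spread passes
  expect_identical(prefilter_dosimeter(make_record(doses = c(50, 52, 48, 51)),
                                       cfg)$decision, "proceed")
  # discordant, but inverting the M30 field's ratios (L1=10, L3=L1*8.88,
  # L2=L3/2.90, L4=L3*0.79)
  doses <- c(10, 88.8 / 2.90, 88.8, 88.8 * 0.79)
  pf <- prefilter_dosimeter(make_record(doses = doses), cfg)
  expect_identical(pf$decision, "proceed")
  expect_false(pf$spread_pass)
  # discordant, matching nothing
  pf2 <- prefilter_dosimeter(make_record(doses = c(100, 1, 100, 1)), cfg)
  expect_identical(pf2$decision, "manual_review")
})
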