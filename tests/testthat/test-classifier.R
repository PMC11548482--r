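test_that("spike detection matches hand-built one- and two-channel spikes", {
  expect_identical(detect_spikes(flat_curve(), 50)$count, 0L)
  one <- detect_spikes(flat_curve(`50` = 200), 50)
  expect_identical(one$count, 1L)
  expect_identical(one$positions, 49L)
  expect_false(one$wide)
  two <- detect_spikes(flat_curve(`50` = 200, `51` = 200), 50)
  expect_identical(two$count, 1L)
  expect_identical(two$positions, 49L)
  expect_true(two$wide)      # fired via the third (two-channel) condition
})

test_that("spike detection agrees with the brute-force triple-condition oracle on random curves", {
  set.seed(21)
  for (i in 1:400) {
    ch <- stats::runif(200, 0, 100)
    if (i %% 3 == 0) ch[sample(195, 4)] <- 500  # guarantee some spikes
    s <- sample(c(20, 50, 80), 1)
    got <- detect_spikes(glow_curve(ch), s)
    want <- oracle_spike_positions(ch, s)
    expect_identical(got$positions, want)
    expect_identical(got$count, oracle_spike_events(want))
  }
})

test_that("class D fires strictly above the spike budget", {
  fake <- function(n) structure(list(positions = seq_len(n) * 5, count = n,
                                     wide = rep(FALSE, n)),
                                class = "spike_report")
  expect_true(classify_class_d(fake(4), 3))
  expect_false(classify_class_d(fake(3), 3))
  expect_false(classify_class_d(fake(0), 3))
})

test_that("smoothing interpolates spike channels and leaves the rest bit-identical", {
  clean <- flat_curve()
  expect_identical(as.numeric(smoothen(clean)), as.numeric(clean))

  one <- flat_curve(`50` = 200)
  sm <- smoothen(one)
  expect_equal(as.numeric(sm)[50], 100)
  expect_identical(as.numeric(sm)[-50], as.numeric(one)[-50])

  two <- flat_curve(`50` = 200, `51` = 200)
  sm2 <- smoothen(two)
  expect_equal(as.numeric(sm2)[50:51], c(100, 100))
  expect_identical(as.numeric(sm2)[-(50:51)], as.numeric(two)[-(50:51)])
})

test_that("smoothing is idempotent once spikes are removed", {
  set.seed(31)
  for (i in 1:20) {
    gc <- generate_normal_gc(seed = NULL, noise_cv = 0)
    spiked <- inject_anomaly(gc, anomaly_spec("D", n_spikes = 2), seed = NULL)
    once <- smoothen(spiked)
    expect_equal(as.numeric(smoothen(once)), as.numeric(once))
  }
})

test_that("class A bands classify constructed pedestals by direct arithmetic", {
  cfg <- gc_config(MinBgdHeight = 10, MaxBgdHeight = 50)
  base <- as.numeric(generate_normal_gc(seed = 3, noise_cv = 0,
                                        shape_jitter = 0, additive_floor = 0))
  high <- base; high[160:200] <- high[160:200] + 150  # avg 15% of max 1000
  expect_identical(classify_class_a(glow_curve(high), cfg), "A_HIGH")
  both <- high; both[1:40] <- both[1:40] + 150
  expect_identical(classify_class_a(glow_curve(both), cfg),
                   c("A_LOW", "A_HIGH"))
  # window average at the max boundary is excluded (strict inequality)
  sat <- base; sat[160:200] <- 0.5 * max(base)
  expect_identical(classify_class_a(glow_curve(sat), cfg), character(0))
  # peak outside 95 +- MaxAllowedShift: never class A
  shifted <- c(high[30:200], rep(high[200], 29))
  expect_identical(classify_class_a(glow_curve(shifted), cfg), character(0))
})

test_that("class C splits on the peak position with lowest-channel tie-break", {
  mk <- function(center) {
    ch <- rep(0, 200); ch[center] <- 100; glow_curve(ch)
  }
  expect_identical(classify_class_c(mk(120), 10), "C_HIGH")
  expect_identical(classify_class_c(mk(70), 10), "C_LOW")
  expect_identical(classify_class_c(mk(95), 10), character(0))
  expect_identical(classify_class_c(mk(105), 10), character(0))  # boundary in
  expect_identical(classify_class_c(mk(106), 10), "C_HIGH")      # boundary out
  tie <- rep(0, 200); tie[c(84, 120)] <- 100                      # argmax -> 84
  expect_identical(classify_class_c(glow_curve(tie), 10), "C_LOW")
})

test_that("class B recognises rectangles as wide and near-deltas as narrow", {
  cfg <- gc_config()
  rect <- rep(0, 200); rect[40:150] <- 100
  # argmax 40 would fail the position precondition; peak the rectangle at 95
  rect[95] <- 101
  expect_identical(classify_class_b(glow_curve(rect), cfg), "B_WIDE")
  delta <- rep(0, 200); delta[94:96] <- c(50, 100, 50)
  expect_identical(classify_class_b(glow_curve(delta), cfg), "B_NARROW")
  normal <- generate_normal_gc(seed = 4, noise_cv = 0)
  expect_identical(classify_class_b(normal, cfg), character(0))
})

test_that("the cascade applies D first and E last, with exclusive outcomes", {
  cfg <- gc_config()
  gc <- generate_normal_gc(seed = 5, noise_cv = 0)
  # spikes AND a shifted peak: D wins outright
  shifted <- inject_anomaly(gc, anomaly_spec("C_HIGH"), seed = 1)
  spiked <- inject_anomaly(shifted, anomaly_spec("D", n_spikes = 5), seed = 2)
  expect_identical(classify_gc(spiked, cfg)$labels, "D")
  # a plain normal shape that reaches the cascade falls through to E
  expect_identical(classify_gc(gc, cfg)$labels, "E")
})

test_that("no outcome ever combines two exclusive classes", {
  set.seed(41)
  labs <- c("A_LOW", "A_HIGH", "B_WIDE", "B_NARROW", "C_LOW", "C_HIGH",
            "D", "E")
  exclusive <- c("B_WIDE", "B_NARROW", "C_LOW", "C_HIGH", "D", "E")
  for (i in 1:120) {
    gc <- generate_normal_gc(seed = NULL)
    if (i %% 2 == 0)
      gc <- inject_anomaly(gc, anomaly_spec(sample(labs, 1)), seed = NULL)
    out <- classify_gc(gc, gc_config())
    expect_lte(sum(out$labels %in% exclusive), 1)
    if (any(out$labels %in% exclusive)) expect_length(out$labels, 1)
    expect_true(all(out$labels %in% labs))
  }
})

test_that("injected labels are recovered by the cascade at zero noise", {
  cfg <- gc_config()
  set.seed(51)
  for (lab in c("A_LOW", "A_HIGH", "C_LOW", "C_HIGH", "D")) {
    for (i in 1:10) {
      gc <- generate_normal_gc(seed = NULL, noise_cv = 0)
      out <- classify_gc(inject_anomaly(gc, anomaly_spec(lab), seed = NULL),
                         cfg)
      expect_true(lab %in% out$labels, label = paste("label", lab))
    }
  }
})
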