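test_that("low-pass filter preserves the passband and kills fast components", {
  # pure 0.05 Hz sinusoid: amplitude preserved within 5%
  slow <- signal_recording(function(t) sin(2 * pi * 0.05 * t))
  fslow <- lowpass(slow, cutoff = 0.3)
  interior <- 200:3500
  expect_gt(max(abs(fslow$data[1, interior])), 0.95)
  expect_lt(max(abs(fslow$data[1, interior])), 1.05)

  # pure 1.0 Hz sinusoid: amplitude reduced by at least 90%
  fast <- signal_recording(function(t) sin(2 * pi * 1.0 * t))
  ffast <- lowpass(fast, cutoff = 0.3)
  expect_lt(max(abs(ffast$data[1, interior])), 0.10)

  # constant signal: DC gain 1 (away from the forward-backward edges)
  dc <- signal_recording(function(t) rep(2.5, length(t)))
  expect_equal(lowpass(dc)$data[, interior], dc$data[, interior],
               tolerance = 1e-6, ignore_attr = TRUE)

  # cutoff at/above Nyquist rejected
  expect_error(lowpass(slow, cutoff = 2.5), "Nyquist")
})

test_that("epoching yields nine 92 s stimulus-aligned epochs", {
  cfg <- tiny_config()
  rec <- generate_nirs_recording(cfg, "ADHD", make_schedule())
  ep <- extract_epochs(rec)
  expect_equal(dim(ep$data), c(9, cfg$nirs_channels, 92 * 5))
  expect_equal(as.vector(table(ep$condition)[c("C", "1B", "2B")]), c(3, 3, 3))

  # epoch content equals the corresponding slice of the continuous record
  tb <- task_blocks(rec$events)
  start <- round((tb$stim_onset[4] - 14) * 5) + 1
  expect_equal(ep$data[4, , ], rec$data[, start:(start + 459)],
               ignore_attr = TRUE)

  # truncated recording: first epoch would start before sample 1
  short <- rec
  short$data <- rec$data[, -(1:100)]
  expect_error(extract_epochs(short), "bounds")
})

test_that("baseline z-scoring matches a hand computation and normalizes its window", {
  cfg <- tiny_config(seed = 11)
  rec <- generate_nirs_recording(cfg, "TD", make_schedule())
  ep <- extract_epochs(rec)
  z <- baseline_zscore(ep)

  # independent recomputation: baseline = 3 s just before the first
  # stimulus, i.e. samples 56..70 of the 14 s pre-window at 5 Hz
  bidx <- 56:70
  for (e in c(1, 5, 9)) {
    raw <- ep$data[e, 2, ]
    m <- mean(raw[bidx]); s <- sd(raw[bidx])
    expect_equal(z$data[e, 2, ], (raw - m) / s, tolerance = 1e-12)
  }
  # Eq. output on its own baseline window: mean 0, SD 1
  for (e in 1:9) for (ch in seq_len(dim(z$data)[2])) {
    expect_lt(abs(mean(z$data[e, ch, bidx])), 1e-9)
    expect_lt(abs(sd(z$data[e, ch, bidx]) - 1), 1e-9)
  }
  # direct substitution: task value 9 under baseline m=5, s=2 gives z=2
  shifted <- ep
  shifted$data[1, 1, ] <- 9
  shifted$data[1, 1, bidx] <- rep(c(5 - 2, 5 + 2), length.out = length(bidx))
  m <- mean(shifted$data[1, 1, bidx]); s <- sd(shifted$data[1, 1, bidx])
  z2 <- baseline_zscore(shifted)
  expect_equal(unname(z2$data[1, 1, 200]), (9 - m) / s, tolerance = 1e-12)

  expect_error(baseline_zscore(z), "already")
})

test_that("zero-SD baselines are excluded loudly", {
  cfg <- tiny_config(noise_sd = 0, drift_slope = 0)
  rec <- generate_nirs_recording(cfg, "TD", make_schedule())
  ep <- extract_epochs(rec)   # flat pre-stimulus baselines in rest epochs
  expect_warning(z <- baseline_zscore(ep), "zero baseline SD")
  expect_true(any(z$excluded))
  expect_true(all(is.na(z$data[which(z$excluded, arr.ind = TRUE)[1, 1],
                               which(z$excluded, arr.ind = TRUE)[1, 2], ])))
})

test_that("condition and grand averaging equal an independent two-stage mean", {
  cfg <- tiny_config(seed = 3)
  rec <- generate_nirs_recording(cfg, "ADHD", make_schedule())
  ep <- baseline_zscore(extract_epochs(rec))
  avg <- average_conditions(ep)

  # brute-force oracle
  for (cc in c("C", "1B", "2B")) {
    sel <- which(ep$condition == cc)
    manual <- (ep$data[sel[1], , ] + ep$data[sel[2], , ] + ep$data[sel[3], , ]) / 3
    expect_equal(avg$condition[[cc]], manual, tolerance = 1e-12)
  }
  expect_equal(avg$grand,
               (avg$condition$C + avg$condition$`1B` + avg$condition$`2B`) / 3,
               tolerance = 1e-12)

  # identical epochs average to any single epoch
  ep2 <- ep
  for (e in 2:9) ep2$data[e, , ] <- ep2$data[1, , ]
  ep2$condition <- rep(c("C", "1B", "2B"), 3)
  avg2 <- average_conditions(ep2)
  expect_equal(avg2$grand, ep2$data[1, , ], tolerance = 1e-12)

  # constant condition curves 1, 2, 3 have grand average 2
  ep3 <- ep2
  ep3$condition <- rep(c("C", "1B", "2B"), each = 3)
  ep3$data[1:3, , ] <- 1; ep3$data[4:6, , ] <- 2; ep3$data[7:9, , ] <- 3
  expect_true(all(average_conditions(ep3)$grand == 2))

  # a missing condition is an error
  ep4 <- ep
  ep4$condition[ep4$condition == "2B"] <- "1B"
  expect_error(average_conditions(ep4), "missing condition")
})

test_that("vectorization is deterministic with the documented length", {
  cfg <- tiny_config()
  rec <- generate_nirs_recording(cfg, "TD", make_schedule())
  avg <- average_conditions(baseline_zscore(extract_epochs(rec)))
  v <- vectorize_response(avg, downsample = 10)
  expect_length(v, cfg$nirs_channels * 46)   # ceiling(460 / 10) = 46
  expect_identical(v, vectorize_response(avg, downsample = 10))
  expect_length(vectorize_response(avg, downsample = 10, mode = "condition"),
                3 * cfg$nirs_channels * 46)

  # two identical subjects produce identical vectors
  tab <- nirs_feature_table(list(rec, rec), c("ADHD", "TD"))
  expect_identical(tab$x[1, ], tab$x[2, ])
  expect_equal(tab$domain, "NIRS_OXY")
})
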