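test_that("I-VT classifies stationary, jumped and sub-minimum streams", {
  # 1 s of stationary samples: one fixation, ~1000 ms, centroid at origin
  s <- data.frame(time_ms = seq(0, 980, 20), x = 0, y = 0, valid = TRUE)
  fx <- classify_fixations(s)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration_ms, 980)
  expect_equal(c(fx$x, fx$y), c(0, 0))

  # two 500 ms clusters joined by a 500 deg/s jump: two fixations
  t <- seq(0, by = 20, length.out = 50)
  s2 <- data.frame(time_ms = c(t, t + 1000),
                   x = c(rep(0, 50), rep(10, 50)), y = 0, valid = TRUE)
  fx2 <- classify_fixations(s2)
  expect_equal(nrow(fx2), 2)
  expect_equal(fx2$x, c(0, 10), tolerance = 1e-12)

  # 40 ms stationary burst flanked by saccades: below minimum duration
  xs <- c(0, 3, 6, 6.01, 6.02, 9, 12)
  s3 <- data.frame(time_ms = seq(0, by = 20, length.out = 7), x = xs, y = 0,
                   valid = TRUE)
  expect_equal(nrow(classify_fixations(s3)), 0)

  # fewer than two valid samples: empty result, not an error
  s4 <- data.frame(time_ms = c(0, 20), x = 0, y = 0, valid = c(TRUE, FALSE))
  expect_equal(nrow(classify_fixations(s4)), 0)
})

test_that("invalid samples break fixation runs unless gap fill bridges them", {
  t <- seq(0, by = 20, length.out = 30)
  v <- rep(TRUE, 30); v[15:16] <- FALSE
  s <- data.frame(time_ms = t, x = 0, y = 0, valid = v)
  expect_equal(nrow(classify_fixations(s)), 2)
  expect_equal(nrow(classify_fixations(s, max_gap_ms = 75)), 1)
})

test_that("gaze sample quality is the valid-sample percentage", {
  s <- data.frame(time_ms = seq(0, 980, 20), x = 0, y = 0, valid = TRUE)
  expect_equal(gaze_sample_quality(s), 100)
  s$valid[1:25] <- FALSE
  expect_equal(gaze_sample_quality(s), 50)
  # a 62% participant falls below the 80% default used by the pipeline
  s2 <- data.frame(time_ms = seq_len(100) * 20, x = 0, y = 0,
                   valid = rep(c(TRUE, FALSE), c(62, 38)))
  expect_lt(gaze_sample_quality(s2), 80)
  expect_error(gaze_sample_quality(s[0, ]), "empty")
})

test_that("AOI assignment honours the orientation mirror", {
  layout <- aoi_layout()
  p <- c(-10, 0)  # inside the CS-left CS rectangle
  expect_equal(assign_aoi(p, layout, "cs_left"), "CS")
  expect_equal(assign_aoi(p, layout, "cs_right"), "UCS")
  expect_equal(assign_aoi(c(0, 0), layout, "cs_left"), "BG")
  expect_error(aoi_layout(cs = c(-5, 5, -4, 4), ucs = c(0, 8, -4, 4)), "disjoint")
})

test_that("window summaries follow the percent/index arithmetic", {
  layout <- aoi_layout()
  trial <- data.frame(cs_offset_ms = 4500, orientation = "cs_left")
  fx <- data.frame(start_ms = c(3000, 3900), end_ms = c(3900, 4500),
                   x = c(-10, 10), y = 0, duration_ms = c(900, 600))
  ws <- window_summary(trial, fx, layout)
  expect_equal(c(ws$pct_cs, ws$pct_ucs, ws$pct_bg), c(60, 40, 0))
  expect_equal(ws$gaze_index, 0.2)

  # all window time on the CS: index saturates at 1
  fx_cs <- data.frame(start_ms = 3000, end_ms = 4500, x = -10, y = 0,
                      duration_ms = 1500)
  expect_equal(window_summary(trial, fx_cs, layout)$gaze_index, 1)

  # no overlap: missing index, zero valid time
  fx_out <- data.frame(start_ms = 0, end_ms = 2000, x = -10, y = 0,
                       duration_ms = 2000)
  ws3 <- window_summary(trial, fx_out, layout)
  expect_true(is.na(ws3$gaze_index))
  expect_equal(ws3$valid_fix_time_ms, 0)

  # fixations straddling the window boundary contribute pro-rated overlap
  fx_str <- data.frame(start_ms = c(2500, 4200), end_ms = c(3500, 5000),
                       x = c(-10, 10), y = 0, duration_ms = c(1000, 800))
  ws4 <- window_summary(trial, fx_str, layout)
  expect_equal(ws4$valid_fix_time_ms, 500 + 300)
  expect_equal(ws4$pct_cs, 100 * 500 / 800)
})

test_that("percent shares sum to 100 and the index stays bounded", {
  cfg <- study_config(seed = 41)
  sched <- gen_trial_schedule(cfg)
  layout <- aoi_layout()
  g <- gen_gaze_session(sched, theta = 0.3, layout, seed = 41)
  summ <- session_summaries(sched, classify_fixations(g), layout)
  pos <- summ[!is.na(summ$gaze_index), ]
  expect_true(nrow(pos) > 40)
  expect_equal(pos$pct_cs + pos$pct_ucs + pos$pct_bg, rep(100, nrow(pos)),
               tolerance = 1e-9)
  expect_true(all(pos$gaze_index >= -1 & pos$gaze_index <= 1))
  eq <- abs(pos$pct_cs - pos$pct_ucs) < 1e-12
  expect_true(all(pos$gaze_index[eq] == 0))
})

test_that("mirroring the stream together with the orientation flag is a no-op", {
  cfg <- study_config(seed = 43)
  sched <- gen_trial_schedule(cfg)
  layout <- aoi_layout()
  g <- gen_gaze_session(sched, theta = 1, layout, seed = 43)
  summ <- session_summaries(sched, classify_fixations(g), layout)

  g_m <- g; g_m$x <- -g_m$x
  sched_m <- sched
  sched_m$orientation <- ifelse(sched$orientation == "cs_left", "cs_right", "cs_left")
  summ_m <- session_summaries(sched_m, classify_fixations(g_m), layout)
  expect_equal(summ$gaze_index, summ_m$gaze_index, tolerance = 1e-12)
  expect_equal(summ$pct_cs, summ_m$pct_cs, tolerance = 1e-12)
})

test_that("trial exclusions keep the first trials of each CS type", {
  cfg <- study_config(seed = 44)
  sched <- gen_trial_schedule(cfg)
  summ <- sched[, c("trial", "shaping", "cs_type", "cs_value", "exp_index")]
  k12 <- apply_exclusions(summ, 12)
  expect_equal(nrow(k12), 48)
  expect_true(all(table(k12$cs_type) == 12))
  # the retained trials are the earliest occurrences of each type
  for (ct in 1:4) {
    all_idx <- sort(summ$exp_index[!summ$shaping & summ$cs_type == ct])
    expect_equal(sort(k12$exp_index[k12$cs_type == ct]), all_idx[1:12])
  }
  expect_equal(nrow(apply_exclusions(summ, 16)), 64)
  expect_equal(nrow(apply_exclusions(summ, 1)), 4)
  expect_warning(out <- apply_exclusions(summ, 20), "fewer")
  expect_equal(nrow(out), 64)
})

test_that("I-VT recovers planted fixations on a noise-free stream", {
  res <- planted_fixation_stream(seed = 7, n_segments = 5)
  fx <- classify_fixations(res$stream)
  expect_equal(nrow(fx), nrow(res$segments))
  expect_equal(fx$start_ms, res$segments$start_ms, tolerance = 1e-9)
  expect_equal(fx$end_ms, res$segments$end_ms, tolerance = 1e-9)
  expect_equal(fx$x, res$segments$x, tolerance = 1e-9)
})
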