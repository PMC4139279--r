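make_schedule <- function() {
  generate_protocol_schedule(synthetic_config(seed = 1))
}

test_that("stable intervals start 30 s after release and end at the next occlusion", {
  sch <- occlusion_schedule(
    data.frame(start_s = c(40, 190), end_s = c(100, 250), phase = "MILD"),
    data.frame(phase = c("BASELINE", "MILD"), start_s = c(0, 40), end_s = c(40, 400)))
  iv <- stable_intervals(sch, "MILD")
  expect_equal(iv$start_s, c(130, 280))
  expect_equal(iv$end_s, c(190, 400))

  # a recovery gap shorter than the margin yields no interval
  sch2 <- occlusion_schedule(
    data.frame(start_s = c(0, 85), end_s = c(60, 145), phase = "MILD"),
    data.frame(phase = "MILD", start_s = 0, end_s = 145))
  iv2 <- stable_intervals(sch2, "MILD")
  expect_equal(nrow(iv2), 0L)

  base <- occlusion_schedule(
    data.frame(start_s = numeric(0), end_s = numeric(0), phase = character(0)),
    data.frame(phase = "BASELINE", start_s = 0, end_s = 1800))
  expect_equal(stable_intervals(base, "BASELINE"),
               data.frame(start_s = 0, end_s = 1800))
})

test_that("occlusions, margins and stable intervals tile each UCO phase", {
  sch <- make_schedule()
  for (phase in c("MILD", "MODERATE", "SEVERE")) {
    ph <- phase_interval(sch, phase)
    ev <- phase_events(sch, phase)
    iv <- stable_intervals(sch, phase)
    occl_time <- sum(ev$end_s - ev$start_s)
    margin_time <- 30 * nrow(ev)
    stable_time <- sum(iv$end_s - iv$start_s)
    lead_in <- ev$start_s[1] - ph[1]
    expect_equal(occl_time + margin_time + stable_time + lead_in, diff(ph))
    # no stable interval overlaps any occlusion
    for (k in seq_len(nrow(iv))) {
      expect_true(all(iv$end_s[k] <= ev$start_s | iv$start_s[k] >= ev$end_s))
    }
  }
})

test_that("aligned extraction pools per-occlusion beats correctly", {
  sch <- occlusion_schedule(
    data.frame(start_s = c(0, 150), end_s = c(60, 210), phase = "MILD"),
    data.frame(phase = "MILD", start_s = 0, end_s = 300))
  ser <- make_series(rep(500, 600))   # 0.5 s beats over 300 s
  on <- extract_aligned_responses(ser, sch, "MILD", "onset")
  expect_equal(nrow(on), 240, tolerance = 0.02)   # 2 x 60 s / 0.5 s
  expect_true(all(on$t_rel >= 0 & on$t_rel <= 60))
  rel <- extract_aligned_responses(ser, sch, "MILD", "release")
  expect_true(all(rel$t_rel >= 0))
  # release points never overlap occlusion windows
  t_abs1 <- rel$t_rel[rel$event == 1] + 60
  expect_true(all(t_abs1 >= 60 & t_abs1 <= 150))
  # pooled multiset equals the union of single-occlusion extractions
  per_event <- lapply(1:2, function(k) {
    sch_k <- occlusion_schedule(sch$events[k, ], sch$phases)
    extract_aligned_responses(ser, sch_k, "MILD", "onset")$rr_ms
  })
  expect_equal(sort(on$rr_ms), sort(unlist(per_event)))
  base_only <- occlusion_schedule(
    data.frame(start_s = numeric(0), end_s = numeric(0), phase = character(0)),
    data.frame(phase = "BASELINE", start_s = 0, end_s = 300))
  expect_error(extract_aligned_responses(ser, base_only, "BASELINE", "onset"),
               "no occlusions")
})

test_that("time constants are recovered exactly on noiseless data", {
  cfg <- quiet_config(seed = 2, tau_stim = 14.22, tau_rec = 5.22)
  sch <- generate_protocol_schedule(cfg)
  ser <- preprocess_series(generate_frr_series(cfg, sch))
  fit <- fit_time_constants(
    extract_aligned_responses(ser, sch, "SEVERE", "onset"),
    extract_aligned_responses(ser, sch, "SEVERE", "release"))
  expect_lt(abs(fit$tau_stim - 14.22) / 14.22, 1e-3)
  expect_lt(abs(fit$tau_rec - 5.22) / 5.22, 1e-3)
  expect_lt(fit$residual_rms, 0.5)
  expect_lt(fit$tau_rec, fit$tau_stim)
  expect_error(fit_time_constants(data.frame(t_rel = 1:3, rr_ms = 1:3),
                                  data.frame(t_rel = 1:20, rr_ms = 1:20)),
               "at least 10")
})

test_that("fits are invariant to occlusion reordering (pooled points)", {
  cfg <- quiet_config(seed = 6, tau_stim = 20, tau_rec = 5, noise_sd = 5)
  sch <- generate_protocol_schedule(cfg)
  ser <- preprocess_series(generate_frr_series(cfg, sch))
  on <- extract_aligned_responses(ser, sch, "SEVERE", "onset")
  re <- extract_aligned_responses(ser, sch, "SEVERE", "release")
  set.seed(1)
  shuf <- function(d) d[sample(nrow(d)), ]
  f1 <- fit_time_constants(on, re)
  f2 <- fit_time_constants(shuf(on), shuf(re))
  expect_equal(f1$tau_stim, f2$tau_stim, tolerance = 1e-9)
  expect_equal(f1$tau_rec, f2$tau_rec, tolerance = 1e-9)
})

test_that("stable-segment concatenation keeps beats, flags and junctions", {
  ser <- make_series(rep(500, 100))
  iv <- data.frame(start_s = c(0, 30), end_s = c(10.25, 45.25))
  st <- concatenate_stable_segments(ser, iv)
  expect_equal(length(unique(st$segment)), 2L)
  b <- segment_boundaries(st)
  expect_length(b, 1L)
  expect_equal(st$segment[b], 2L)
  n1 <- sum(ser$time_s >= 0 & ser$time_s < 10.25)
  expect_equal(b, n1 + 1L)
  expect_equal(nrow(st), sum(ser$time_s >= 30 & ser$time_s < 45.25) + n1)
  one <- concatenate_stable_segments(ser, data.frame(start_s = 0, end_s = 20))
  expect_length(segment_boundaries(one), 0L)
  expect_error(concatenate_stable_segments(ser, iv[0, ]), "no intervals")
  # retained beat-time equals the per-interval sums (direct oracle)
  manual <- sum(vapply(seq_len(nrow(iv)), function(k) {
    sum(ser$time_s >= iv$start_s[k] & ser$time_s < iv$end_s[k]) * 0.5
  }, numeric(1)))
  expect_equal(nrow(st) * 0.5, manual)
})

test_that("phase analysis windows take the last 30 minutes and match biomarkers", {
  sch <- occlusion_schedule(
    data.frame(start_s = numeric(0), end_s = numeric(0), phase = character(0)),
    data.frame(phase = c("BASELINE", "MILD"), start_s = c(0, 1800),
               end_s = c(1800, 5400)))
  bm <- validate_biomarkers(data.frame(
    time_s = seq(0, 5400, by = 1200), pH = seq(7.35, 7.30, length.out = 5),
    lactate = rep(2, 5), base_deficit = rep(0, 5)))
  pw <- phase_analysis_window(sch, bm, "MILD")
  expect_equal(pw$window, c(3600, 5400))
  expect_equal(pw$biomarker$time_s, 4800)   # last sample at/below phase end
  expect_warning(phase_analysis_window(sch, bm, "BASELINE", window_s = 3600),
                 "shorter than the analysis window")
  early <- validate_biomarkers(data.frame(time_s = 100, pH = 7.3,
                                          lactate = 1, base_deficit = 0))
  expect_error(phase_analysis_window(sch, early, "MILD"), "no biomarker")
})
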