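#' Empirical ranges for the occlusion-response time constants (s)
#'
#' Published per-subject ranges of the exponential time constant of the fetal
#' RR response to cord-occlusion onset (`stim`) and release (`rec`) in the
#' seven-sheep UCO cohort; used as the default sampling ranges for synthetic
#' subjects.
#' @export
TAU_STIM_RANGE <- c(9.63, 46.17)

#' @rdname TAU_STIM_RANGE
#' @export
TAU_REC_RANGE <- c(3.38, 7.88)

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for a synthetic UCO subject
#'
#' Defines one simulated fetal sheep under the repetitive
#' umbilical-cord-occlusion protocol: 1-min occlusions alternating with
#' 1.5-min recoveries through MILD (60 min), MODERATE (60 min) and SEVERE
#' (~2 h) phases, flanked by baseline and recovery rest periods.
#'
#' All randomness derives from `seed`: the subject's time constants are drawn
#' at construction (stream `10*seed + 3`), beat-to-beat noise uses stream
#' `10*seed + 1` and artifact placement stream `10*seed + 2`.
#'
#' @param seed integer seed; drives every random component.
#' @param baseline_rr_ms mean baseline fetal RR interval (ms).
#' @param phase_durations_s named numeric vector of phase durations
#'   (seconds) over `BASELINE`, `MILD`, `MODERATE`, `SEVERE`, `RECOVERY`.
#' @param occlusion_s,recovery_s occlusion and recovery durations of one UCO
#'   cycle (seconds).
#' @param decel_depth_ms named vector: plateau RR elevation (ms) of the
#'   occlusion-induced deceleration in each UCO phase.
#' @param tau_stim,tau_rec exponential time constants (s) of deceleration
#'   onset and recovery; `NULL` draws them uniformly from the empirical
#'   ranges [TAU_STIM_RANGE] / [TAU_REC_RANGE].
#' @param osc_period_s period (s) of the slow baseline heart-rate oscillation.
#' @param osc_amp_ms named vector of per-phase amplitudes (ms) of that
#'   oscillation.
#' @param noise_sd_ms named vector of per-phase beat-to-beat white-noise
#'   standard deviations (ms).
#' @param artifact_rate_per_h expected beat-misdetection artifacts per hour.
#' @param biomarker_targets data frame with columns `phase`, `pH`, `lactate`,
#'   `base_deficit`: acid-base values reached at the END of each phase;
#'   the trajectory is piecewise linear between phase ends and flat over
#'   BASELINE.
#' @param subject_id subject label.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             baseline_rr_ms = 400,
                             phase_durations_s = c(BASELINE = 1800, MILD = 3600,
                                                   MODERATE = 3600, SEVERE = 7200,
                                                   RECOVERY = 1800),
                             occlusion_s = 60,
                             recovery_s = 90,
                             decel_depth_ms = c(MILD = 40, MODERATE = 120, SEVERE = 250),
                             tau_stim = NULL,
                             tau_rec = NULL,
                             osc_period_s = 30,
                             osc_amp_ms = c(BASELINE = 8, MILD = 6, MODERATE = 12,
                                            SEVERE = 20, RECOVERY = 8),
                             noise_sd_ms = c(BASELINE = 3, MILD = 2.5, MODERATE = 5.5,
                                             SEVERE = 9, RECOVERY = 3),
                             artifact_rate_per_h = 6,
                             biomarker_targets = NULL,
                             subject_id = paste0("synthetic-", seed)) {
  if (is.null(tau_stim) || is.null(tau_rec)) {
    taus <- with_local_seed(10L * as.integer(seed) + 3L, {
      c(stats::runif(1, TAU_STIM_RANGE[1], TAU_STIM_RANGE[2]),
        stats::runif(1, TAU_REC_RANGE[1], TAU_REC_RANGE[2]))
    })
    if (is.null(tau_stim)) tau_stim <- taus[1]
    if (is.null(tau_rec)) tau_rec <- taus[2]
  }
  if (is.null(biomarker_targets)) {
    biomarker_targets <- data.frame(
      phase = PHASE_LEVELS,
      pH = c(7.34, 7.33, 7.28, 6.98, 7.25),
      lactate = c(1.60, 1.65, 3.80, 11.40, 6.00),
      base_deficit = c(1.08, 0.29, -2.46, -14.07, -8.00)
    )
  }
  cfg <- structure(list(
    seed = as.integer(seed),
    baseline_rr_ms = baseline_rr_ms,
    phase_durations_s = phase_durations_s[PHASE_LEVELS],
    occlusion_s = occlusion_s,
    recovery_s = recovery_s,
    decel_depth_ms = decel_depth_ms,
    tau_stim = tau_stim,
    tau_rec = tau_rec,
    osc_period_s = osc_period_s,
    osc_amp_ms = osc_amp_ms,
    noise_sd_ms = noise_sd_ms,
    artifact_rate_per_h = artifact_rate_per_h,
    biomarker_targets = biomarker_targets,
    subject_id = subject_id
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  if (any(is.na(cfg$phase_durations_s)) || any(cfg$phase_durations_s <= 0)) {
    stop("all phase durations must be positive")
  }
  if (!(cfg$tau_stim > cfg$tau_rec && cfg$tau_rec > 0)) {
    stop("time constants must satisfy tau_stim > tau_rec > 0")
  }
  if (cfg$occlusion_s <= 0 || cfg$recovery_s <= 0) stop("cycle durations must be positive")
  sev <- cfg$biomarker_targets$pH[cfg$biomarker_targets$phase == "SEVERE"]
  if (length(sev) != 1L || sev >= 7.00) {
    stop("SEVERE terminal pH target must be below 7.00")
  }
  if (cfg$artifact_rate_per_h < 0) stop("artifact rate must be non-negative")
  cfg
}

#' Generate the occlusion schedule of the synthetic protocol
#'
#' Phases are laid out back-to-back in protocol order.  Each UCO phase is
#' tiled with (occlusion, recovery) cycles; a trailing partial cycle is
#' dropped.  BASELINE and RECOVERY carry no occlusions.
#'
#' @param config a [synthetic_config()].
#' @return an [occlusion_schedule()].
#' @export
generate_protocol_schedule <- function(config) {
  durs <- config$phase_durations_s
  starts <- cumsum(c(0, durs[-length(durs)]))
  names(starts) <- names(durs)
  phases <- data.frame(phase = names(durs), start_s = unname(starts),
                       end_s = unname(starts + durs))
  cycle <- config$occlusion_s + config$recovery_s
  ev <- list()
  for (ph in c("MILD", "MODERATE", "SEVERE")) {
    n_cyc <- floor(durs[[ph]] / cycle)
    if (n_cyc < 1L) stop("phase ", ph, " shorter than one occlusion cycle")
    s0 <- starts[[ph]] + cycle * seq_len(n_cyc) - cycle
    ev[[ph]] <- data.frame(start_s = s0, end_s = s0 + config$occlusion_s, phase = ph)
  }
  events <- do.call(rbind, ev)
  rownames(events) <- NULL
  occlusion_schedule(events, phases)
}

# Deterministic RR component (ms) at time t: baseline + occlusion-induced
# deceleration (saturating exponential onset, exponential recovery) + slow
# oscillation. `ev` is the event table, `depth` per-event plateau depth.
synthetic_rr_det <- function(t, config, ev, phase_of_t) {
  rr <- rep(config$baseline_rr_ms, length(t))
  ph <- phase_of_t(t)
  amp <- config$osc_amp_ms[ph]
  rr <- rr + amp * sin(2 * pi * t / config$osc_period_s)
  if (nrow(ev) > 0L) {
    k <- findInterval(t, ev$start_s)   # last event started at or before t
    has <- k >= 1L
    if (any(has)) {
      kk <- k[has]
      tt <- t[has]
      depth <- config$decel_depth_ms[ev$phase[kk]]
      t0 <- ev$start_s[kk]
      t1 <- ev$end_s[kk]
      inside <- tt <= t1
      contrib <- numeric(length(tt))
      contrib[inside] <- depth[inside] * (1 - exp(-(tt[inside] - t0[inside]) / config$tau_stim))
      at_release <- depth * (1 - exp(-(t1 - t0) / config$tau_stim))
      contrib[!inside] <- at_release[!inside] * exp(-(tt[!inside] - t1[!inside]) / config$tau_rec)
      rr[has] <- rr[has] + contrib
    }
  }
  rr
}

#' Generate a synthetic fetal RR series
#'
#' Beats are generated sequentially over the full protocol: the RR interval
#' at time t is the deterministic response (baseline + occlusion deceleration
#' + slow oscillation) plus per-phase white noise, and the next beat onset
#' follows after rr/1000 seconds.  During an occlusion starting at t0 the
#' deceleration builds as `depth * (1 - exp(-(t - t0)/tau_stim))` and decays
#' after release with time constant `tau_rec`.  The same seed always yields
#' the identical series.
#'
#' @param config a [synthetic_config()].
#' @param schedule the matching [generate_protocol_schedule()] output.
#' @return an [rr_series()], all beats original and anchor-eligible.
#' @export
generate_frr_series <- function(config, schedule) {
  total_end <- max(schedule$phases$end_s)
  ph <- schedule$phases[order(schedule$phases$start_s), ]
  phase_of_t <- function(t) {
    i <- pmax(1L, findInterval(t, ph$start_s))
    ph$phase[i]
  }
  ev <- schedule$events
  n_max <- ceiling(total_end / ((config$baseline_rr_ms - 50) / 1000)) + 16L
  with_local_seed(10L * config$seed + 1L, {
    noise_pool <- stats::rnorm(n_max)
    time_s <- numeric(n_max)
    rr_ms <- numeric(n_max)
    t <- 0
    i <- 0L
    while (t < total_end) {
      i <- i + 1L
      det <- synthetic_rr_det(t, config, ev, phase_of_t)
      sd_ph <- config$noise_sd_ms[phase_of_t(t)]
      rr <- det + sd_ph * noise_pool[i]
      rr <- max(rr, 150)  # physiologic floor, keeps rr > 0
      time_s[i] <- t
      rr_ms[i] <- rr
      t <- t + rr / 1000
    }
    # rr of beat i is the interval ending at beat i: shift so that
    # time_s[i+1]-time_s[i] == rr_ms[i+1]/1000 holds exactly.
    rr_series(time_s = time_s[seq_len(i)],
              rr_ms = c(rr_ms[1], rr_ms[seq_len(i - 1L)]),
              subject_id = config$subject_id)
  })
}

#' Inject beat-misdetection artifacts into an RR series
#'
#' Emulates missed QRS detections: randomly chosen runs of consecutive beats
#' are replaced by a single merged interval equal to the sum of the replaced
#' RRs (always > 1500 ms), conserving total recording duration.  The number
#' of artifacts is Poisson with mean `artifact_rate_per_h` times the
#' recording duration.  Provenance flags are left untouched — labelling
#' artifacts is the preprocessing step's job.
#'
#' @param series an `rr_series`.
#' @param config a [synthetic_config()] (supplies the rate).
#' @param seed integer seed for placement; defaults to the config's artifact
#'   stream.
#' @return an `rr_series` with merged artifact intervals.
#' @export
inject_artifacts <- function(series, config, seed = 10L * config$seed + 2L) {
  rate <- config$artifact_rate_per_h
  if (rate == 0) return(series)
  dur_h <- (max(series$time_s) - min(series$time_s)) / 3600
  with_local_seed(seed, {
    n_art <- stats::rpois(1, rate * dur_h)
    if (n_art == 0L) return(series)
    n <- nrow(series)
    starts <- sort(sample(seq(50L, n - 100L), n_art))
    runs <- list()
    last_end <- 0L
    for (s0 in starts) {
      if (s0 <= last_end + 1L) next
      # extend the run until the merged interval exceeds the artifact
      # threshold, plus 0-2 extra beats
      csum <- cumsum(series$rr_ms[s0:min(n, s0 + 30L)])
      len <- which(csum > 1500)[1]
      if (is.na(len)) next
      len <- len + sample(0:2, 1)
      if (s0 + len - 1L > n - 50L) next
      runs[[length(runs) + 1L]] <- c(s0, s0 + len - 1L)
      last_end <- s0 + len - 1L
    }
    if (!length(runs)) return(series)
    rr <- series$rr_ms
    drop <- logical(n)
    for (r in rev(runs)) {
      rr[r[2]] <- sum(rr[r[1]:r[2]])
      drop[r[1]:(r[2] - 1L)] <- TRUE
    }
    out <- series[!drop, , drop = FALSE]
    out$rr_ms <- rr[!drop]
    rownames(out) <- NULL
    attr(out, "subject_id") <- subject_id(series)
    class(out) <- c("rr_series", "data.frame")
    rebuild_times(out)
  })
}

#' Generate the acid-base biomarker trajectory
#'
#' Samples are taken every 20 minutes from the start of the recording,
#' mirroring the blood-sampling schedule of the UCO experiments.  Values are
#' held at the baseline target throughout BASELINE and interpolate linearly
#' between the per-phase-end targets thereafter.
#'
#' @param config a [synthetic_config()].
#' @param schedule the protocol schedule.
#' @param interval_s sampling interval (default 1200 s = 20 min).
#' @return a `biomarker_samples` data frame.
#' @export
generate_biomarker_trajectory <- function(config, schedule, interval_s = 1200) {
  total_end <- max(schedule$phases$end_s)
  times <- seq(0, total_end, by = interval_s)
  tg <- config$biomarker_targets
  tg <- tg[match(schedule$phases$phase, tg$phase), ]
  # The SEVERE phase is terminated by the blood sample that first shows the
  # target acidemia, so its target is reached at the last sampling time
  # inside the phase rather than at the nominal phase end.
  node_end <- schedule$phases$end_s
  i_sev <- which(schedule$phases$phase == "SEVERE")
  if (length(i_sev) == 1L) {
    last_sample <- floor(node_end[i_sev] / interval_s) * interval_s
    if (last_sample > schedule$phases$start_s[i_sev]) node_end[i_sev] <- last_sample
  }
  node_t <- c(0, node_end)
  base_row <- tg[tg$phase == "BASELINE", ]
  out <- data.frame(time_s = times)
  for (col in c("pH", "lactate", "base_deficit")) {
    node_v <- c(base_row[[col]], tg[[col]])
    out[[col]] <- stats::approx(node_t, node_v, xout = times, rule = 2)$y
  }
  validate_biomarkers(out)
}

#' Simulate one synthetic subject
#'
#' Convenience wrapper: schedule, fetal RR series with injected artifacts,
#' and biomarker trajectory for one configuration.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `config`, `schedule`, `series`, `biomarkers`.
#' @export
simulate_subject <- function(config) {
  schedule <- generate_protocol_schedule(config)
  series <- generate_frr_series(config, schedule)
  series <- inject_artifacts(series, config)
  biomarkers <- generate_biomarker_trajectory(config, schedule)
  list(config = config, schedule = schedule, series = series,
       biomarkers = biomarkers)
}

#' Simulate a synthetic cohort
#'
#' Subject j receives seed `seed + j`, so the whole cohort is reproducible
#' from one integer.
#'
#' @param n_subjects number of subjects (default 7, the analysed cohort size).
#' @param seed cohort base seed.
#' @param ... further arguments passed to [synthetic_config()].
#' @return list of [simulate_subject()] results.
#' @export
simulate_cohort <- function(n_subjects = 7, seed = 1L, ...) {
  lapply(seq_len(n_subjects), function(j) {
    simulate_subject(synthetic_config(seed = as.integer(seed) + j,
                                      subject_id = sprintf("sheep-%02d", j), ...))
  })
}
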