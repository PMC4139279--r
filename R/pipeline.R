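#' Load one subject from CSV files
#'
#' @param rr_path RR-series CSV (see [read_rr_series()]).
#' @param schedule_path occlusion-schedule CSV (see
#'   [read_occlusion_schedule()]).
#' @param biomarkers_path biomarker CSV (see [read_biomarkers()]).
#' @param phase_path optional companion phase table.
#' @param subject_id optional subject label.
#' @return list with `series`, `schedule`, `biomarkers`.
#' @export
load_subject <- function(rr_path, schedule_path, biomarkers_path,
                         phase_path = NULL, subject_id = NULL) {
  list(series = read_rr_series(rr_path, subject_id = subject_id),
       schedule = read_occlusion_schedule(schedule_path, phase_path),
       biomarkers = read_biomarkers(biomarkers_path))
}

uco_phases <- c("BASELINE", "MILD", "MODERATE", "SEVERE")

# Per-subject capacity spectra for both variants over the phase analysis
# windows. Returns a long data frame.
subject_capacities <- function(subj, t_max, L, min_anchors, window_s, margin_s,
                               allow_cross_boundary) {
  series <- subj$prep
  schedule <- subj$schedule
  rows <- list()
  for (phase in uco_phases) {
    pw <- suppressWarnings(
      phase_analysis_window(schedule, subj$biomarkers, phase, window_s = window_s)
    )
    win <- pw$window
    entire <- window_series(series, win)
    st_int <- stable_intervals(schedule, phase, margin_s = margin_s)
    st_int$start_s <- pmax(st_int$start_s, win[1])
    st_int$end_s <- pmin(st_int$end_s, win[2])
    st_int <- st_int[st_int$end_s > st_int$start_s, , drop = FALSE]
    stable <- concatenate_stable_segments(series, st_int)
    for (variant in c("entire", "stable")) {
      x <- if (variant == "entire") entire else stable
      spec <- capacity_spectrum(x, T_values = seq_len(t_max), L = L,
                                min_anchors = min_anchors,
                                allow_cross_boundary = allow_cross_boundary)
      spec$subject <- subject_id(series)
      spec$phase <- phase
      spec$variant <- variant
      rows[[paste(phase, variant)]] <- spec
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Paired Wilcoxon across subjects for every T, one comparison definition.
per_T_comparison <- function(caps, col, variant, phase_a, phase_b, t_max,
                             bonferroni_factor, alpha) {
  p <- rep(NA_real_, t_max)
  for (T in seq_len(t_max)) {
    a <- caps[caps$phase == phase_a & caps$variant == variant & caps$T == T, ]
    b <- caps[caps$phase == phase_b & caps$variant == variant & caps$T == T, ]
    m <- merge(a[, c("subject", col)], b[, c("subject", col)], by = "subject")
    if (nrow(m) >= 5L && !anyNA(m[, 2:3])) {
      p[T] <- tryCatch(wilcoxon_signed_rank(m[[2]], m[[3]])$p, error = function(e) NA_real_)
    }
  }
  data.frame(T = seq_len(t_max), p_raw = p,
             p_corrected = pmin(1, p * bonferroni_factor))
}

#' Run the full UCO PRSA analysis
#'
#' End-to-end cohort analysis: preprocessing (artifact reconstruction,
#' anchor exclusions), quality control (subjects need more than `qc_min`
#' correctly-located beat time in MODERATE and SEVERE), per-phase analysis
#' windows (last `window_s` seconds), AC/DC spectra for T = 1..`t_max` on
#' both the entire windows and the concatenated stable (deceleration-free)
#' segments, occlusion/recovery time-constant fits, per-T paired Wilcoxon
#' phase comparisons with Bonferroni correction, Spearman correlations of
#' AC/DC with the time-matched acid-base biomarkers, SDNN, and an optional
#' post-SEVERE 5-minute window comparison against BASELINE.
#'
#' @param cohort list of subjects, each a list with `series`
#'   (raw `rr_series`), `schedule`, `biomarkers` — e.g. from
#'   [simulate_cohort()] or [load_subject()].
#' @param t_max largest anchor-filter length T (default 50).
#' @param L PRSA window half-length (default 50 beats).
#' @param min_anchors reliability threshold on anchor counts (default 150).
#' @param window_s phase analysis window (default 1800 s).
#' @param margin_s post-release stable margin (default 30 s).
#' @param qc_min minimum beat-quality fraction, strict (default 0.9).
#' @param alpha significance level (default 0.05).
#' @param bonferroni_factor correction factor for the three consecutive-phase
#'   comparisons (default 3).
#' @param fit_phase phase whose occlusions feed the exponential fit
#'   (default `"SEVERE"`).
#' @param include_baseline_in_correlation pool BASELINE points into the
#'   biomarker correlations (default `TRUE`).
#' @param post_severe_window_s length of the post-SEVERE comparison window
#'   (default 300 s; `NULL` disables it).
#' @param allow_cross_boundary let PRSA windows span stable-segment junctions.
#' @param out_dir if non-`NULL`, write all report tables as CSV here.
#' @param verbose emit one progress message per subject and stage.
#' @return object of class `uco_prsa_report`: a list with elements
#'   `capacities`, `qc`, `tau_table`, `tau_summary`, `tau_models`,
#'   `phase_comparisons`, `significant_ranges`, `correlations`,
#'   `biomarker_summary`, `sdnn_table`, `post_severe`, `settings`.
#' @export
run_full_analysis <- function(cohort,
                              t_max = 50L, L = 50L, min_anchors = 150L,
                              window_s = 1800, margin_s = 30,
                              qc_min = 0.9, alpha = 0.05, bonferroni_factor = 3,
                              fit_phase = "SEVERE",
                              include_baseline_in_correlation = TRUE,
                              post_severe_window_s = 300,
                              allow_cross_boundary = FALSE,
                              out_dir = NULL, verbose = FALSE) {
  stopifnot(length(cohort) >= 1L)
  say <- function(...) if (verbose) message(sprintf(...))

  # --- preprocessing and QC -------------------------------------------------
  qc_rows <- list()
  subjects <- list()
  for (subj in cohort) {
    sid <- subject_id(subj$series)
    subj$prep <- preprocess_series(subj$series)
    fr_mod <- beat_quality_fraction(subj$prep, phase_interval(subj$schedule, "MODERATE"))
    fr_sev <- beat_quality_fraction(subj$prep, phase_interval(subj$schedule, "SEVERE"))
    included <- fr_mod > qc_min && fr_sev > qc_min
    qc_rows[[sid]] <- data.frame(subject = sid, quality_moderate = fr_mod,
                                 quality_severe = fr_sev, included = included)
    say("qc %s: moderate %.4f severe %.4f -> %s", sid, fr_mod, fr_sev,
        if (included) "included" else "EXCLUDED")
    if (included) subjects[[sid]] <- subj
  }
  qc <- do.call(rbind, qc_rows)
  rownames(qc) <- NULL
  if (length(subjects) == 0L) stop("all subjects excluded by quality control")

  # --- per-subject capacities, tau fits, SDNN ------------------------------
  caps <- list()
  tau_rows <- list()
  tau_models <- list()
  sdnn_rows <- list()
  post_rows <- list()
  for (subj in subjects) {
    sid <- subject_id(subj$series)
    say("capacities %s", sid)
    caps[[sid]] <- subject_capacities(subj, t_max, L, min_anchors, window_s,
                                      margin_s, allow_cross_boundary)
    on_pts <- extract_aligned_responses(subj$prep, subj$schedule, fit_phase, "onset")
    re_pts <- extract_aligned_responses(subj$prep, subj$schedule, fit_phase, "release")
    fit <- fit_time_constants(on_pts, re_pts)
    tau_models[[sid]] <- fit
    tau_rows[[sid]] <- data.frame(subject = sid, tau_stim = fit$tau_stim,
                                  tau_rec = fit$tau_rec, A = fit$A, B = fit$B,
                                  C = fit$C, D = fit$D,
                                  residual_rms = fit$residual_rms,
                                  n_points = fit$n_points)
    say("tau %s: stim %.2f rec %.2f", sid, fit$tau_stim, fit$tau_rec)
    for (phase in uco_phases) {
      pw <- suppressWarnings(phase_analysis_window(subj$schedule, subj$biomarkers,
                                                   phase, window_s = window_s))
      st_int <- stable_intervals(subj$schedule, phase, margin_s = margin_s)
      st_int$start_s <- pmax(st_int$start_s, pw$window[1])
      st_int$end_s <- pmin(st_int$end_s, pw$window[2])
      st_int <- st_int[st_int$end_s > st_int$start_s, , drop = FALSE]
      st <- concatenate_stable_segments(subj$prep, st_int)
      sdnn_rows[[paste(sid, phase)]] <- data.frame(
        subject = sid, phase = phase, sdnn_ms = sdnn(st),
        pH = pw$biomarker$pH, lactate = pw$biomarker$lactate,
        base_deficit = pw$biomarker$base_deficit)
    }
    if (!is.null(post_severe_window_s)) {
      sev_end <- phase_interval(subj$schedule, "SEVERE")[2]
      post <- window_series(subj$prep, c(sev_end, sev_end + post_severe_window_s))
      spec <- capacity_spectrum(post, T_values = seq_len(t_max), L = L,
                                min_anchors = min_anchors)
      spec$subject <- sid
      spec$phase <- "POST_SEVERE"
      spec$variant <- "entire"
      post_rows[[sid]] <- spec
    }
  }
  capacities <- do.call(rbind, caps)
  rownames(capacities) <- NULL
  tau_table <- do.call(rbind, tau_rows)
  rownames(tau_table) <- NULL
  sdnn_table <- do.call(rbind, sdnn_rows)
  rownames(sdnn_table) <- NULL

  tau_summary <- rbind(
    data.frame(parameter = "tau_stim", t(quartile_summary(tau_table$tau_stim))),
    data.frame(parameter = "tau_rec", t(quartile_summary(tau_table$tau_rec)))
  )

  # --- phase comparisons ----------------------------------------------------
  pairs <- list(c("BASELINE", "MILD"), c("MILD", "MODERATE"),
                c("MODERATE", "SEVERE"))
  comp_rows <- list()
  range_rows <- list()
  for (variant in c("entire", "stable")) {
    for (cap_col in c("AC_abs_ms", "DC_abs_ms")) {
      cap_name <- if (cap_col == "AC_abs_ms") "AC" else "DC"
      for (pr in pairs) {
        say("comparison %s %s %s-%s", variant, cap_name, pr[1], pr[2])
        tab <- per_T_comparison(capacities, cap_col, variant, pr[1], pr[2],
                                t_max, bonferroni_factor, alpha)
        tab$capacity <- cap_name
        tab$variant <- variant
        tab$pair <- paste(pr, collapse = "-")
        comp_rows[[paste(variant, cap_name, tab$pair[1])]] <- tab
        rng <- significant_T_ranges(tab$p_raw, alpha = alpha,
                                    bonferroni_factor = bonferroni_factor)
        if (nrow(rng) > 0L) {
          rng$capacity <- cap_name; rng$variant <- variant
          rng$pair <- tab$pair[1]
          range_rows[[paste(variant, cap_name, tab$pair[1])]] <- rng
        }
      }
    }
  }
  phase_comparisons <- do.call(rbind, comp_rows)
  rownames(phase_comparisons) <- NULL
  significant_ranges <- if (length(range_rows)) {
    z <- do.call(rbind, range_rows); rownames(z) <- NULL; z
  } else data.frame(T_from = integer(0), T_to = integer(0),
                    capacity = character(0), variant = character(0),
                    pair = character(0))

  # --- biomarker correlations ----------------------------------------------
  corr_phases <- if (include_baseline_in_correlation) uco_phases else setdiff(uco_phases, "BASELINE")
  corr_rows <- list()
  for (variant in c("entire", "stable")) {
    for (cap_col in c("AC_abs_ms", "DC_abs_ms")) {
      cap_name <- if (cap_col == "AC_abs_ms") "AC" else "DC"
      for (T in seq_len(t_max)) {
        sub <- capacities[capacities$variant == variant & capacities$T == T &
                            capacities$phase %in% corr_phases,
                          c("subject", "phase", cap_col)]
        m <- merge(sub, sdnn_table[, c("subject", "phase", "pH", "lactate", "base_deficit")],
                   by = c("subject", "phase"))
        for (bm in c("pH", "lactate", "base_deficit")) {
          ok <- stats::complete.cases(m[[cap_col]], m[[bm]])
          if (sum(ok) >= 3L) {
            ct <- tryCatch(spearman_cor(m[[cap_col]][ok], m[[bm]][ok]),
                           error = function(e) NULL)
            if (!is.null(ct)) {
              corr_rows[[paste(variant, cap_name, T, bm)]] <- data.frame(
                capacity = cap_name, variant = variant, T = T, biomarker = bm,
                rho = ct$rho, p = ct$p, n = ct$n)
            }
          }
        }
      }
    }
  }
  correlations <- do.call(rbind, corr_rows)
  rownames(correlations) <- NULL

  # --- biomarker summary (per-phase cohort medians) -------------------------
  bm_rows <- list()
  for (phase in uco_phases) {
    sub <- sdnn_table[sdnn_table$phase == phase, ]
    for (bm in c("pH", "lactate", "base_deficit")) {
      q <- quartile_summary(sub[[bm]])
      bm_rows[[paste(phase, bm)]] <- data.frame(
        phase = phase, biomarker = bm, median = q[["median"]],
        q1 = q[["q1"]], q3 = q[["q3"]], n = nrow(sub))
    }
  }
  biomarker_summary <- do.call(rbind, bm_rows)
  rownames(biomarker_summary) <- NULL

  post_severe <- if (length(post_rows)) {
    z <- do.call(rbind, post_rows); rownames(z) <- NULL; z
  } else NULL

  report <- structure(list(
    capacities = capacities, qc = qc,
    tau_table = tau_table, tau_summary = tau_summary, tau_models = tau_models,
    phase_comparisons = phase_comparisons,
    significant_ranges = significant_ranges,
    correlations = correlations,
    biomarker_summary = biomarker_summary,
    sdnn_table = sdnn_table,
    post_severe = post_severe,
    settings = list(t_max = t_max, L = L, min_anchors = min_anchors,
                    window_s = window_s, margin_s = margin_s, qc_min = qc_min,
                    alpha = alpha, bonferroni_factor = bonferroni_factor,
                    fit_phase = fit_phase,
                    include_baseline_in_correlation = include_baseline_in_correlation,
                    n_subjects_in = length(cohort),
                    n_subjects_analysed = length(subjects))
  ), class = "uco_prsa_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Cohort medians of AC/DC per phase
#'
#' Table of cohort median and quartiles of the absolute capacities for
#' selected T values, one row per (capacity, variant, T, phase).
#'
#' @param report a `uco_prsa_report`.
#' @param T_values which T rows to tabulate (default `c(2, 4, 6, 10, 20)`).
#' @return data frame.
#' @export
capacity_medians <- function(report, T_values = c(2, 4, 6, 10, 20)) {
  caps <- report$capacities
  rows <- list()
  for (variant in unique(caps$variant)) {
    for (cap_col in c("AC_abs_ms", "DC_abs_ms")) {
      cap_name <- if (cap_col == "AC_abs_ms") "AC" else "DC"
      for (T in T_values) {
        for (phase in uco_phases) {
          v <- caps[caps$variant == variant & caps$T == T & caps$phase == phase, cap_col]
          v <- v[!is.na(v)]
          if (length(v) == 0L) next
          q <- quartile_summary(v)
          rows[[paste(variant, cap_name, T, phase)]] <- data.frame(
            capacity = cap_name, variant = variant, T = T, phase = phase,
            median = q[["median"]], q1 = q[["q1"]], q3 = q[["q3"]], n = length(v))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.uco_prsa_report <- function(x, ...) {
  cat(sprintf("uco_prsa_report: %d/%d subjects analysed, T = 1..%d\n",
              x$settings$n_subjects_analysed, x$settings$n_subjects_in,
              x$settings$t_max))
  cat(sprintf("  tau_stim median %.2f s, tau_rec median %.2f s\n",
              x$tau_summary$median[x$tau_summary$parameter == "tau_stim"],
              x$tau_summary$median[x$tau_summary$parameter == "tau_rec"]))
  cat(sprintf("  %d significant T-range rows, %d correlation rows\n",
              nrow(x$significant_ranges), nrow(x$correlations)))
  invisible(x)
}

#' Write all report tables to a directory
#'
#' @param report a `uco_prsa_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE, quote = FALSE)
    }
  }
  caps <- report$capacities
  caps_out <- caps[, c("subject", "phase", "variant", "T", "s",
                       "AC_abs_ms", "DC_abs_ms", "n_anchors_dec", "n_anchors_acc",
                       "unreliable_acc", "unreliable_dec")]
  write_capacity_table(caps_out, file.path(out_dir, "capacities.csv"))
  w(report$qc, "qc.csv")
  w(report$tau_table, "tau_table.csv")
  w(report$tau_summary, "tau_summary.csv")
  w(report$phase_comparisons, "phase_comparisons.csv")
  w(report$significant_ranges, "significant_T_ranges.csv")
  w(report$correlations, "correlations.csv")
  w(report$biomarker_summary, "biomarker_summary.csv")
  w(report$sdnn_table, "sdnn.csv")
  w(report$post_severe, "post_severe_capacities.csv")
  w(capacity_medians(report), "capacity_medians.csv")
  s <- report$settings
  writeLines(c("prsafhr run manifest",
               sprintf("package_version: %s",
                       as.character(utils::packageVersion("prsafhr"))),
               sprintf("%s: %s", names(s), unlist(lapply(s, paste, collapse = ",")))),
             file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
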