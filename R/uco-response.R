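#' Pool beats aligned to occlusion onset or release
#'
#' For every occlusion of a phase, collects the RR intervals whose span
#' starts inside the occlusion (`alignment = "onset"`, relative time measured
#' from occlusion start) or inside the following recovery gap
#' (`alignment = "release"`, relative time from occlusion end, up to the next
#' occlusion or the phase end).  Each RR interval is timestamped at the
#' interval's start (`time_s - rr_ms/1000`), the moment the autonomic state
#' it reflects was in force.  The pooled points are what the exponential
#' response model is fitted to.
#'
#' @param series an `rr_series`.
#' @param schedule an `occlusion_schedule`.
#' @param phase phase label containing at least one occlusion.
#' @param alignment `"onset"` or `"release"`.
#' @return data frame with columns `t_rel` (s), `rr_ms`, `event` (occlusion
#'   index within the phase).
#' @export
extract_aligned_responses <- function(series, schedule, phase,
                                      alignment = c("onset", "release")) {
  alignment <- match.arg(alignment)
  ev <- phase_events(schedule, phase)
  if (nrow(ev) == 0L) stop("no occlusions in phase ", phase)
  ph_end <- phase_interval(schedule, phase)[2]
  t_beat <- series$time_s - series$rr_ms / 1000
  out <- vector("list", nrow(ev))
  for (k in seq_len(nrow(ev))) {
    if (alignment == "onset") {
      a <- ev$start_s[k]; b <- ev$end_s[k]
    } else {
      a <- ev$end_s[k]
      b <- if (k < nrow(ev)) ev$start_s[k + 1L] else ph_end
    }
    sel <- t_beat >= a & t_beat <= b
    if (any(sel)) {
      out[[k]] <- data.frame(t_rel = t_beat[sel] - a,
                             rr_ms = series$rr_ms[sel], event = k)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L) stop("no beats found in ", alignment, " windows")
  rownames(res) <- NULL
  res
}

# One exponential branch fit by Levenberg-Marquardt with deterministic
# initialization and bounded restarts on tau.
fit_exp_branch <- function(points, kind = c("onset", "release")) {
  kind <- match.arg(kind)
  if (nrow(points) < 10L) stop("need at least 10 points per branch")
  pts <- points[order(points$t_rel), ]
  span <- max(pts$t_rel) - min(pts$t_rel)
  if (span <= 0) stop("degenerate branch: no time spread")
  k10 <- max(1L, min(10L, nrow(pts)))
  offset0 <- if (kind == "onset") {
    stats::median(utils::head(pts$rr_ms, k10))   # value at occlusion start
  } else {
    stats::median(utils::tail(pts$rr_ms, k10))   # asymptote after recovery
  }
  amp0 <- max(diff(range(pts$rr_ms)), 1)
  tau_grid <- (span / 3) * c(1, 0.3, 3)
  form <- if (kind == "onset") {
    rr_ms ~ A + B * (1 - exp(-t_rel / tau))
  } else {
    rr_ms ~ C + D * exp(-t_rel / tau)
  }
  best <- NULL
  for (tau0 in tau_grid) {
    st <- if (kind == "onset") list(A = offset0, B = amp0, tau = tau0)
          else list(C = offset0, D = amp0, tau = tau0)
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = pts, start = st,
                        lower = c(-Inf, -Inf, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-9) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("exponential fit failed to converge on ", kind,
         " branch (n = ", nrow(pts), ", span = ", signif(span, 4), " s)")
  }
  cf <- stats::coef(best$fit)
  list(coef = cf, rss = best$rss, n = nrow(pts),
       tau_at_bound = cf[["tau"]] <= 1.5e-3)
}

#' Fit the occlusion-response time constants
#'
#' Two independent nonlinear least-squares fits (Levenberg-Marquardt):
#' `rr(t) = A + B (1 - exp(-t/tau_stim))` on the onset-aligned points and
#' `rr(t) = C + D exp(-t/tau_rec)` on the release-aligned points.  A, B, C,
#' D are nuisance scalars; tau_stim and tau_rec characterise how fast the
#' heart rate decelerates under occlusion and how fast it recovers after
#' release.  Initialization is deterministic (branch-endpoint median offset,
#' range amplitude, tau = span/3 with x0.3/x3 restarts), so results are
#' reproducible.
#'
#' @param onset_points,release_points data frames with `t_rel`, `rr_ms`
#'   (see [extract_aligned_responses()]); at least 10 points each.
#' @return object of class `uco_response_model`: `A`, `B`, `C`, `D` (ms),
#'   `tau_stim`, `tau_rec` (s), `residual_rms` (ms), `n_points`,
#'   `tau_at_bound` flags.
#' @export
fit_time_constants <- function(onset_points, release_points) {
  on <- fit_exp_branch(onset_points, "onset")
  re <- fit_exp_branch(release_points, "release")
  structure(list(
    A = unname(on$coef[["A"]]), B = unname(on$coef[["B"]]),
    C = unname(re$coef[["C"]]), D = unname(re$coef[["D"]]),
    tau_stim = unname(on$coef[["tau"]]), tau_rec = unname(re$coef[["tau"]]),
    residual_rms = sqrt((on$rss + re$rss) / (on$n + re$n)),
    n_points = on$n + re$n,
    tau_at_bound = c(stim = on$tau_at_bound, rec = re$tau_at_bound)
  ), class = "uco_response_model")
}

#' @export
print.uco_response_model <- function(x, ...) {
  cat(sprintf("uco_response_model: tau_stim = %.2f s, tau_rec = %.2f s (n = %d, RMS = %.2f ms)\n",
              x$tau_stim, x$tau_rec, x$n_points, x$residual_rms))
  invisible(x)
}

#' Deceleration-free ("stable") intervals of a phase
#'
#' For each occlusion ending at e and the next occlusion starting at s', the
#' interval `[e + margin, s')` is stable; after the last occlusion the
#' interval runs to the phase end.  The default 30 s margin exceeds three
#' times the longest recovery time constant, so the heart rate is back at
#' baseline.  Non-positive intervals are omitted.  A phase without
#' occlusions (BASELINE, RECOVERY) is one whole stable interval.
#'
#' @param schedule an `occlusion_schedule`.
#' @param phase phase label.
#' @param margin_s post-release margin in seconds (default 30).
#' @return data frame with columns `start_s`, `end_s`.
#' @export
stable_intervals <- function(schedule, phase, margin_s = 30) {
  ph <- phase_interval(schedule, phase)
  ev <- phase_events(schedule, phase)
  if (nrow(ev) == 0L) {
    return(data.frame(start_s = ph[1], end_s = ph[2]))
  }
  starts <- ev$end_s + margin_s
  ends <- c(ev$start_s[-1L], ph[2])
  keep <- ends > starts
  data.frame(start_s = starts[keep], end_s = ends[keep])
}

#' Concatenate stable segments of an RR series
#'
#' Retains, in order, the beats whose onsets fall inside each interval and
#' joins them into one series whose `segment` column records the junctions;
#' provenance and anchor flags are carried over.  PRSA anchor selection will
#' not span a junction unless explicitly allowed.
#'
#' @param series an `rr_series`.
#' @param intervals data frame with `start_s`, `end_s`, ordered and
#'   non-overlapping.
#' @return an `rr_series` with one segment per non-empty interval.
#' @export
concatenate_stable_segments <- function(series, intervals) {
  if (NROW(intervals) == 0L) stop("no intervals selected")
  if (is.unsorted(intervals$start_s, strictly = TRUE)) stop("intervals must be ordered")
  pieces <- list()
  seg <- 0L
  for (k in seq_len(nrow(intervals))) {
    sel <- series$time_s >= intervals$start_s[k] & series$time_s < intervals$end_s[k]
    if (any(sel)) {
      seg <- seg + 1L
      p <- series[sel, , drop = FALSE]
      p$segment <- seg
      pieces[[seg]] <- p
    }
  }
  if (seg == 0L) stop("no beats inside the stable intervals")
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "subject_id") <- subject_id(series)
  class(out) <- c("rr_series", "data.frame")
  validate_rr_series(out)
  out
}

#' Analysis window and time-matched biomarker of a phase
#'
#' The analysis window is the last `window_s` seconds of the phase (clipped
#' at the phase start, with a warning, for short phases), where the
#' hypoxic-acidemic load of the phase is maximal.  The matched biomarker is
#' the last blood sample drawn at or before the phase end.
#'
#' @param schedule an `occlusion_schedule`.
#' @param biomarkers a `biomarker_samples` data frame.
#' @param phase phase label.
#' @param window_s window length in seconds (default 1800 = 30 min).
#' @return list of class `phase_window`: `phase`, `window` (c(start, end)),
#'   `biomarker` (one-row data frame).
#' @export
phase_analysis_window <- function(schedule, biomarkers, phase, window_s = 1800) {
  ph <- phase_interval(schedule, phase)
  start <- ph[2] - window_s
  if (start < ph[1]) {
    warning("phase ", phase, " shorter than the analysis window; using whole phase")
    start <- ph[1]
  }
  idx <- which(biomarkers$time_s <= ph[2])
  if (length(idx) == 0L || biomarkers$time_s[max(idx)] < ph[1]) {
    stop("no biomarker sample within phase ", phase)
  }
  structure(list(phase = phase, window = c(start, ph[2]),
                 biomarker = biomarkers[max(idx), , drop = FALSE]),
            class = "phase_window")
}
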