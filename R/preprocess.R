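#' Label and reconstruct RR artifacts
#'
#' RR intervals longer than `threshold_ms` (default 1500 ms, i.e. below
#' 40 bpm) are treated as beat-misdetection artifacts.  Each maximal run of
#' artifact intervals is merged into one gap of duration G and substituted
#' with an equivalent number of beats: n = round(G / m) with n >= 1, where m
#' is the median of the 20 nearby original RR samples (10 before and 10 after
#' the gap, fewer at record edges).  The inserted beats all get rr = G/n so
#' total recording time is conserved; they are flagged `reconstructed` and
#' anchor-ineligible.
#'
#' @param series a contiguous (single-segment) `rr_series`.
#' @param threshold_ms artifact threshold in ms.
#' @return an `rr_series` with artifacts substituted.
#' @export
reconstruct_artifacts <- function(series, threshold_ms = 1500) {
  stopifnot(inherits(series, "rr_series"))
  if (length(unique(series$segment)) != 1L) {
    stop("reconstruct_artifacts expects a contiguous series")
  }
  is_art <- series$rr_ms > threshold_ms
  if (all(is_art)) stop("series is entirely artifact")
  if (!any(is_art)) return(series)

  r <- rle(is_art)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  art_runs <- which(r$values)

  pieces <- list()
  prev_end <- 0L
  pc <- 0L
  for (k in art_runs) {
    a <- run_start[k]; b <- run_end[k]
    if (a > prev_end + 1L) {
      pc <- pc + 1L
      pieces[[pc]] <- series[(prev_end + 1L):(a - 1L), , drop = FALSE]
    }
    G <- sum(series$rr_ms[a:b])
    before <- series$rr_ms[seq_len(a - 1L)][!is_art[seq_len(a - 1L)]]
    after <- if (b < nrow(series)) series$rr_ms[(b + 1L):nrow(series)][!is_art[(b + 1L):nrow(series)]] else numeric(0)
    nb <- utils::tail(before, 10)
    na_ <- utils::head(after, 10)
    if (length(nb) + length(na_) < 1L) stop("no valid neighbours around artifact gap")
    m <- stats::median(c(nb, na_))
    n_new <- max(1L, round(G / m))
    pc <- pc + 1L
    pieces[[pc]] <- data.frame(
      time_s = rep(NA_real_, n_new),            # rebuilt below
      rr_ms = rep(G / n_new, n_new),
      provenance = "reconstructed",
      anchor_eligible = FALSE,
      segment = series$segment[a]
    )
    prev_end <- b
  }
  if (prev_end < nrow(series)) {
    pc <- pc + 1L
    pieces[[pc]] <- series[(prev_end + 1L):nrow(series), , drop = FALSE]
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  # rebuild onsets anchored at the start of the record's first interval, so
  # the final onset is conserved even when the record opens with a gap
  out$time_s[1] <- series$time_s[1] - series$rr_ms[1] / 1000 + out$rr_ms[1] / 1000
  attr(out, "subject_id") <- subject_id(series)
  class(out) <- c("rr_series", "data.frame")
  out <- rebuild_times(out)
  validate_rr_series(out)
  out
}

#' Mark anchor-point exclusions
#'
#' A beat is excluded from serving as a PRSA anchor when its RR interval
#' exceeds the immediately preceding one by more than `jump_fraction`
#' (default 20%, increases only) or when it is a reconstructed sample.  The
#' first beat of each segment has no predecessor and is ineligible.  Excluded
#' beats still contribute their RR values to the moving averages and PRSA
#' windows around other anchors.
#'
#' @param series an `rr_series`, artifacts already reconstructed.
#' @param jump_fraction relative increase above which a beat is excluded.
#' @return the series with `anchor_eligible` recomputed.
#' @export
mark_anchor_exclusions <- function(series, jump_fraction = 0.2) {
  stopifnot(inherits(series, "rr_series"))
  n <- nrow(series)
  eligible <- rep(TRUE, n)
  if (n > 1L) {
    jump <- c(FALSE, series$rr_ms[-1L] > (1 + jump_fraction) * series$rr_ms[-n])
    eligible <- eligible & !jump
  }
  eligible[1L] <- FALSE
  if (n > 1L) eligible[c(1L, segment_boundaries(series))] <- FALSE
  eligible[series$provenance == "reconstructed"] <- FALSE
  series$anchor_eligible <- eligible
  series
}

#' Fraction of a window covered by correctly detected beats
#'
#' Each beat covers the RR interval ending at its onset; the quality fraction
#' is the window time covered by original (non-reconstructed) beats divided
#' by the window length.  Subjects with a fraction below 0.9 in the MODERATE
#' or SEVERE phase are excluded from cohort analysis (strictly more than 90%
#' of beats must be correctly located).
#'
#' @param series an `rr_series` (after [reconstruct_artifacts()]).
#' @param window numeric `c(start, end)` seconds.
#' @return fraction in `[0, 1]`.
#' @export
beat_quality_fraction <- function(series, window) {
  stopifnot(length(window) == 2L)
  if (window[2] <= window[1]) stop("empty window")
  beat_start <- series$time_s - series$rr_ms / 1000
  beat_end <- series$time_s
  ov <- pmin(beat_end, window[2]) - pmax(beat_start, window[1])
  ov[ov < 0] <- 0
  covered <- sum(ov[series$provenance == "original"])
  min(1, covered / (window[2] - window[1]))
}

#' Standard preprocessing chain
#'
#' Artifact reconstruction followed by anchor-exclusion marking.
#'
#' @param series raw `rr_series`.
#' @param artifact_threshold_ms artifact threshold (ms).
#' @param jump_fraction anchor-exclusion jump threshold.
#' @return preprocessed `rr_series`.
#' @export
preprocess_series <- function(series, artifact_threshold_ms = 1500,
                              jump_fraction = 0.2) {
  mark_anchor_exclusions(
    reconstruct_artifacts(series, threshold_ms = artifact_threshold_ms),
    jump_fraction = jump_fraction
  )
}
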