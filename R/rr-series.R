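#' Fetal RR-interval series
#'
#' An `rr_series` is a data frame of ordered beats with one row per beat and
#' columns:
#' \describe{
#'   \item{time_s}{beat onset time in seconds from the start of the recording}
#'   \item{rr_ms}{RR interval ending at this beat, in milliseconds}
#'   \item{provenance}{`"original"` or `"reconstructed"` (artifact
#'     substitution, see [reconstruct_artifacts()])}
#'   \item{anchor_eligible}{logical; whether the beat may serve as a PRSA
#'     anchor point (see [mark_anchor_exclusions()])}
#'   \item{segment}{integer segment id; consecutive ids mark junctions where
#'     non-adjacent pieces of the recording were concatenated
#'     (see [concatenate_stable_segments()])}
#' }
#' Within a contiguous segment the onset times must be strictly increasing
#' and consistent with the RR intervals: `time_s[i+1] - time_s[i]` equals
#' `rr_ms[i+1]/1000` to within 1 ms.  The RR interval of the first beat of a
#' segment has no predecessor and is unconstrained.
#'
#' @param time_s numeric vector of beat onset times (s).
#' @param rr_ms numeric vector of RR intervals (ms), same length.
#' @param provenance character vector, `"original"` or `"reconstructed"`.
#' @param anchor_eligible logical vector.
#' @param segment integer vector of segment ids (non-decreasing).
#' @param subject_id single string identifying the subject.
#' @param validate logical; check invariants (default `TRUE`).
#'
#' @return An object of class `rr_series` (a data frame).
#' @export
rr_series <- function(time_s, rr_ms,
                      provenance = rep("original", length(time_s)),
                      anchor_eligible = rep(TRUE, length(time_s)),
                      segment = rep(1L, length(time_s)),
                      subject_id = "subject",
                      validate = TRUE) {
  x <- data.frame(
    time_s = as.numeric(time_s),
    rr_ms = as.numeric(rr_ms),
    provenance = as.character(provenance),
    anchor_eligible = as.logical(anchor_eligible),
    segment = as.integer(segment)
  )
  attr(x, "subject_id") <- as.character(subject_id)
  class(x) <- c("rr_series", "data.frame")
  if (validate) validate_rr_series(x)
  x
}

#' Validate an RR series
#'
#' Checks the `rr_series` invariants and stops with an informative message
#' naming the first offending row on violation.
#'
#' @param x an `rr_series`.
#' @return `x`, invisibly.
#' @export
validate_rr_series <- function(x) {
  stopifnot(inherits(x, "rr_series"))
  n <- nrow(x)
  if (n == 0L) stop("rr_series has no beats")
  if (any(!is.finite(x$rr_ms)) || any(!is.finite(x$time_s))) {
    stop("non-finite value at row ", which(!is.finite(x$rr_ms) | !is.finite(x$time_s))[1])
  }
  if (any(x$rr_ms <= 0)) {
    stop("non-positive RR interval at row ", which(x$rr_ms <= 0)[1])
  }
  if (is.unsorted(x$segment)) stop("segment ids must be non-decreasing")
  if (n > 1L) {
    same_seg <- x$segment[-1L] == x$segment[-n]
    dt <- diff(x$time_s)
    bad <- same_seg & dt <= 0
    if (any(bad)) {
      stop("onset times not strictly increasing at row ", which(bad)[1] + 1L)
    }
    # rr[i+1] must equal the onset-time step within 1 ms inside a segment
    mismatch <- same_seg & abs(dt * 1000 - x$rr_ms[-1L]) > 1
    if (any(mismatch)) {
      stop("rr_ms inconsistent with onset-time step at row ", which(mismatch)[1] + 1L)
    }
  }
  if (any(x$provenance == "reconstructed" & x$anchor_eligible)) {
    stop("reconstructed beat marked anchor-eligible at row ",
         which(x$provenance == "reconstructed" & x$anchor_eligible)[1])
  }
  invisible(x)
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("rr_series: %d beats, %.1f s, subject '%s', %d segment(s)\n",
              nrow(x), diff(range(x$time_s)), subject_id(x),
              length(unique(x$segment))))
  cat(sprintf("  original %d / reconstructed %d; anchor-eligible %d\n",
              sum(x$provenance == "original"),
              sum(x$provenance == "reconstructed"),
              sum(x$anchor_eligible)))
  invisible(x)
}

#' Subject id of an RR series
#' @param x an `rr_series`.
#' @return character scalar.
#' @export
subject_id <- function(x) {
  id <- attr(x, "subject_id")
  if (is.null(id)) "subject" else id
}

#' Indices of segment junctions
#'
#' Beat indices at which a new concatenated segment starts (the first segment
#' does not count).  Empty for contiguous recordings.
#'
#' @param x an `rr_series`.
#' @return integer vector of beat indices.
#' @export
segment_boundaries <- function(x) {
  which(diff(x$segment) != 0L) + 1L
}

#' Restrict an RR series to a time window
#'
#' Keeps beats with onset time inside `[start, end)`.  Segment ids and flags
#' are carried over unchanged.
#'
#' @param x an `rr_series`.
#' @param window numeric length-2 vector `c(start, end)` in seconds.
#' @return an `rr_series`.
#' @export
window_series <- function(x, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  keep <- x$time_s >= window[1] & x$time_s < window[2]
  if (!any(keep)) stop("no beats inside window [", window[1], ", ", window[2], ")")
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "subject_id") <- subject_id(x)
  class(out) <- c("rr_series", "data.frame")
  out
}

# Recompute onset times from RR intervals, preserving the first onset of each
# segment. Used after editing rr_ms so the timing invariant holds again.
rebuild_times <- function(x) {
  t <- x$time_s
  for (seg in unique(x$segment)) {
    idx <- which(x$segment == seg)
    if (length(idx) > 1L) {
      t[idx] <- t[idx[1]] + c(0, cumsum(x$rr_ms[idx[-1L]])) / 1000
    }
  }
  x$time_s <- t
  x
}
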