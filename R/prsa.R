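#' Select PRSA anchor points
#'
#' Beat i is a deceleration anchor when the mean of the T intervals starting
#' at i exceeds the mean of the T intervals immediately preceding it
#' (RR lengthening); acceleration anchors use the reverse strict inequality.
#' Ties are never anchors.  Beats flagged `anchor_eligible = FALSE` (jump
#' artifacts, reconstructed samples) are never anchors themselves, but their
#' RR values still enter the moving averages around neighbouring candidates.
#' A candidate is only admissible when both T-averages and the full +/-L
#' PRSA window fit inside one contiguous segment (disable with
#' `allow_cross_boundary = TRUE`).
#'
#' @param series a preprocessed `rr_series`.
#' @param T moving-average filter length in beats (>= 1).
#' @param mode `"deceleration"` or `"acceleration"`.
#' @param L PRSA window half-length in beats.
#' @param allow_cross_boundary let averages and windows span concatenation
#'   junctions (mimics anchor selection across consecutive recovery periods).
#' @return integer vector of anchor beat indices, ascending.
#' @export
select_anchor_points <- function(series, T, mode = c("deceleration", "acceleration"),
                                 L = 50L, allow_cross_boundary = FALSE) {
  mode <- match.arg(mode)
  stopifnot(T >= 1L, L >= 1L)
  rr <- series$rr_ms
  n <- length(rr)
  M <- max(T, L)
  if (n < 2L * M + 1L) {
    stop("series too short for T = ", T, ", L = ", L,
         " (need at least ", 2L * M + 1L, " beats, have ", n, ")")
  }
  i <- (M + 1L):(n - M + 1L)
  cs <- c(0, cumsum(rr))
  after <- (cs[i + T] - cs[i]) / T          # mean rr[i .. i+T-1]
  before <- (cs[i] - cs[i - T]) / T         # mean rr[i-T .. i-1]
  hit <- if (mode == "deceleration") after > before else after < before
  hit <- hit & series$anchor_eligible[i]
  if (!allow_cross_boundary) {
    hit <- hit & series$segment[i - M] == series$segment[i + M - 1L]
  }
  i[hit]
}

#' Build the PRSA curve
#'
#' Windows of 2L beats (anchor at position L+1, index k = 0) are extracted
#' around every anchor, aligned and averaged: X(k) = mean over anchors of
#' rr[anchor + k], for k = -L .. L-1.
#'
#' @param series an `rr_series`.
#' @param anchors integer anchor indices from [select_anchor_points()].
#' @param L window half-length in beats.
#' @return object of class `prsa_curve`: list with `values` (named numeric,
#'   length 2L), `n_anchors`, `L`.
#' @export
compute_prsa_curve <- function(series, anchors, L = 50L) {
  if (length(anchors) == 0L) stop("no anchor points: PRSA curve undefined")
  rr <- series$rr_ms
  offsets <- seq.int(-L, L - 1L)
  if (min(anchors) - L < 1L || max(anchors) + L - 1L > length(rr)) {
    stop("anchor without a full +/-L window")
  }
  idx <- rep(anchors, each = length(offsets)) + offsets
  m <- matrix(rr[idx], nrow = length(offsets))
  values <- rowMeans(m)
  names(values) <- offsets
  structure(list(values = values, n_anchors = length(anchors), L = L),
            class = "prsa_curve")
}

#' @export
print.prsa_curve <- function(x, ...) {
  cat(sprintf("prsa_curve: 2L = %d samples, %d anchors, X(0) = %.3f ms\n",
              2L * x$L, x$n_anchors, x$values[as.character(0)]))
  invisible(x)
}

#' Haar-wavelet capacity of a PRSA curve
#'
#' The acceleration/deceleration capacity is the Haar-wavelet coefficient of
#' the PRSA curve at scale s and the anchor location:
#' `(sum of X(0..s-1) - sum of X(-s..-1)) / (2 s)`.
#' On deceleration-anchored curves the value is typically positive, on
#' acceleration-anchored curves negative; downstream tables store absolute
#' values.
#'
#' @param curve a `prsa_curve`.
#' @param s wavelet scale in beats, `1 <= s <= L`.
#' @return signed capacity in ms.
#' @export
compute_capacity <- function(curve, s) {
  stopifnot(s >= 1L, s <= curve$L)
  X <- curve$values
  pos <- X[as.character(0:(s - 1L))]
  neg <- X[as.character((-s):(-1L))]
  (sum(pos) - sum(neg)) / (2 * s)
}

#' AC/DC over a spectrum of T values
#'
#' Computes deceleration and acceleration capacity for each T with the
#' wavelet scale tied to the filter length (s = T), the convention used for
#' fetal RR analysis.  Entries whose anchor count does not exceed
#' `min_anchors` are flagged `unreliable` rather than dropped; T values with
#' no anchors at all yield `NA` capacities.
#'
#' @param series preprocessed `rr_series`.
#' @param T_values integer vector of filter lengths (default 1:50).
#' @param L window half-length (must cover `max(T_values)`).
#' @param min_anchors reliability threshold: strictly more anchors than this
#'   are required (default 150).
#' @param allow_cross_boundary see [select_anchor_points()].
#' @return data frame with one row per T: `T`, `s`, `AC_ms`, `DC_ms` (signed),
#'   `AC_abs_ms`, `DC_abs_ms`, `n_anchors_acc`, `n_anchors_dec`,
#'   `unreliable_acc`, `unreliable_dec`.
#' @export
capacity_spectrum <- function(series, T_values = 1:50, L = 50L,
                              min_anchors = 150L, allow_cross_boundary = FALSE) {
  stopifnot(max(T_values) <= L)
  one <- function(T) {
    cap <- c(deceleration = NA_real_, acceleration = NA_real_)
    n_anc <- c(deceleration = 0L, acceleration = 0L)
    for (mode in names(cap)) {
      anchors <- select_anchor_points(series, T = T, mode = mode, L = L,
                                      allow_cross_boundary = allow_cross_boundary)
      n_anc[mode] <- length(anchors)
      if (length(anchors) > 0L) {
        cap[mode] <- compute_capacity(compute_prsa_curve(series, anchors, L = L), s = T)
      }
    }
    data.frame(T = T, s = T,
               AC_ms = cap[["acceleration"]], DC_ms = cap[["deceleration"]],
               AC_abs_ms = abs(cap[["acceleration"]]),
               DC_abs_ms = abs(cap[["deceleration"]]),
               n_anchors_acc = n_anc[["acceleration"]],
               n_anchors_dec = n_anc[["deceleration"]],
               unreliable_acc = n_anc[["acceleration"]] <= min_anchors,
               unreliable_dec = n_anc[["deceleration"]] <= min_anchors)
  }
  out <- do.call(rbind, lapply(T_values, one))
  rownames(out) <- NULL
  out
}

#' Approximate low-pass cutoff of the anchor filter
#'
#' The T-beat moving average used in anchor detection acts as a low-pass
#' filter whose 3 dB pass-band ends at approximately `1 / (2 T rr)` Hz, where
#' rr is the mean RR interval in seconds.
#'
#' @param T filter length in beats.
#' @param mean_rr_s mean RR interval in seconds.
#' @return cutoff frequency in Hz.
#' @export
t_to_cutoff_frequency <- function(T, mean_rr_s) {
  stopifnot(T >= 1, mean_rr_s > 0)
  1 / (2 * T * mean_rr_s)
}
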