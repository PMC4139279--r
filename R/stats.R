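# All permutations of 1..n as a matrix (n! rows). Used only for small n in
# the exact Spearman null.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    blk <- matrix(rest[sub], nrow(sub), n - 1L)
    out[row + seq_len(nrow(sub)), ] <- cbind(k, blk)
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation with an exact small-sample p-value
#'
#' rho is the Pearson correlation of mid-ranks (ties averaged).  The
#' two-sided p-value is an exact permutation p (all n! orderings of one
#' margin) for n below `exact_max_n`, and the usual t-approximation on
#' `rho * sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param x,y numeric vectors of equal length, n >= 3, no missing values.
#' @param exact_max_n enumerate the permutation null for `n < exact_max_n`
#'   (default 10).
#' @return list with `rho`, `p`, `n`, `exact` (logical).
#' @export
spearman_cor <- function(x, y, exact_max_n = 10L) {
  stopifnot(length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined correlation: zero variance in ranks")
  }
  rho <- stats::cor(rx, ry)
  if (n < exact_max_n) {
    perms <- all_permutations(n)
    # rho is affine in S = sum(rx_perm * ry); enumerate S over all orderings
    S <- as.vector(matrix(rx[perms], nrow(perms), n) %*% ry)
    mS <- mean(S)
    obs <- sum(rx * ry)
    p <- mean(abs(S - mS) >= abs(obs - mS) - 1e-9)
    list(rho = rho, p = p, n = n, exact = TRUE)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    list(rho = rho, p = min(1, p), n = n, exact = FALSE)
  }
}

# Exact two-sided p for the signed-rank statistic by dynamic programming over
# the (doubled, so integer-valued even with midranks) ranks of |d|.
signed_rank_exact_p <- function(ranks2, w2) {
  total <- sum(ranks2)
  dist <- numeric(total + 1L)   # dist[v+1] = #subsets with doubled sum v
  dist[1L] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), dist[seq_len(total + 1L - r)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  v <- 0:total
  mu <- total / 2
  sum(dist[abs(v - mu) >= abs(w2 - mu) - 1e-9])
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences.  Zero differences are dropped.  For
#' n (after zero removal) up to `exact_max_n` the p-value is exact,
#' enumerating the sign-flip null distribution of the signed-rank statistic
#' (mid-ranks for tied magnitudes); beyond that, a normal approximation with
#' continuity and tie correction is used.
#'
#' @param a,b numeric vectors of equal length (paired observations).
#' @param exact_max_n largest n for the exact null (default 25).
#' @return list with `p`, `statistic` (W+, sum of positive-difference
#'   ranks), `n`, `exact`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max_n = 25L) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate input: all paired differences are zero")
  if (n < 5L) stop("need at least 5 non-zero paired differences, have ", n)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max_n) {
    p <- signed_rank_exact_p(as.integer(round(2 * r)), 2 * w)
    list(p = p, statistic = w, n = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    # tie correction on the variance
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    list(p = min(1, 2 * stats::pnorm(-abs(z))), statistic = w, n = n, exact = FALSE)
  }
}

#' Contiguous T-ranges with a significant corrected p-value
#'
#' Applies a Bonferroni factor (default 3, one per consecutive-phase
#' comparison) to per-T p-values and returns the maximal runs of T at which
#' the corrected p is below `alpha`.
#'
#' @param p_values numeric vector of raw p-values, named or indexed by T.
#' @param alpha significance level (default 0.05).
#' @param bonferroni_factor multiplicative correction (default 3).
#' @param T_values the T value of each entry (default `seq_along(p_values)`).
#' @return data frame with columns `T_from`, `T_to` (possibly zero rows).
#' @export
significant_T_ranges <- function(p_values, alpha = 0.05, bonferroni_factor = 3,
                                 T_values = seq_along(p_values)) {
  corrected <- pmin(1, p_values * bonferroni_factor)
  sig <- !is.na(corrected) & corrected < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(T_from = T_values[starts[keep]], T_to = T_values[ends[keep]])
}

#' Median, quartiles and mean
#'
#' Quartiles use linear interpolation at positions `1 + p (n - 1)` (R's
#' default quantile type 7), the convention that reproduces published
#' interquartile ranges for small physiological cohorts.
#'
#' @param values numeric vector, n >= 1.
#' @return named numeric: `median`, `q1`, `q3`, `mean`.
#' @export
quartile_summary <- function(values) {
  stopifnot(length(values) >= 1L)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3], mean = mean(values))
}

#' SDNN of an RR series
#'
#' Sample standard deviation (n-1 denominator) of the RR intervals of
#' original (non-reconstructed) beats, optionally restricted to a time
#' window; a total-variability index.
#'
#' @param series an `rr_series`.
#' @param window optional `c(start, end)` in seconds.
#' @return SDNN in ms.
#' @export
sdnn <- function(series, window = NULL) {
  x <- series
  if (!is.null(window)) x <- window_series(x, window)
  rr <- x$rr_ms[x$provenance == "original"]
  if (length(rr) < 2L) stop("need at least 2 original beats")
  stats::sd(rr)
}
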