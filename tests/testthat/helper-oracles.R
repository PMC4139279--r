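# Fixture builders and brute-force oracles, kept deliberately naive and
# independent of the package's streaming implementations.

# rr_series from a plain RR vector (ms), contiguous timing.
make_series <- function(rr_ms, eligible = NULL, provenance = NULL,
                        segment = NULL, subject_id = "fixture") {
  n <- length(rr_ms)
  time_s <- cumsum(rr_ms) / 1000
  rr_series(
    time_s = time_s, rr_ms = rr_ms,
    provenance = if (is.null(provenance)) rep("original", n) else provenance,
    anchor_eligible = if (is.null(eligible)) c(FALSE, rep(TRUE, n - 1L)) else eligible,
    segment = if (is.null(segment)) rep(1L, n) else segment,
    subject_id = subject_id
  )
}

# Naive PRSA: scan every index, materialize every window, average, then apply
# the Haar difference. Returns list(anchors, capacity) or NA capacity.
prsa_oracle <- function(series, T, s, L, mode) {
  rr <- series$rr_ms
  n <- length(rr)
  M <- max(T, L)
  anchors <- integer(0)
  for (i in seq_len(n)) {
    if (i - M < 1 || i + M - 1 > n) next
    if (!series$anchor_eligible[i]) next
    if (series$segment[i - M] != series$segment[i + M - 1]) next
    after <- mean(rr[i:(i + T - 1)])
    before <- mean(rr[(i - T):(i - 1)])
    hit <- if (mode == "deceleration") after > before else after < before
    if (hit) anchors <- c(anchors, i)
  }
  if (length(anchors) == 0L) return(list(anchors = anchors, capacity = NA_real_))
  windows <- t(vapply(anchors, function(a) rr[(a - L):(a + L - 1)], numeric(2 * L)))
  X <- colMeans(windows)
  k <- seq(-L, L - 1)
  cap <- (sum(X[k >= 0 & k <= s - 1]) - sum(X[k >= -s & k <= -1])) / (2 * s)
  list(anchors = anchors, capacity = cap)
}

# Exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign flips.
wilcoxon_enum_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu <- sum(r) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Exact two-sided Spearman p by enumerating all n! orderings, computing the
# correlation of mid-ranks directly for each.
spearman_enum_oracle <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- permutations_oracle(n)
  rho_all <- apply(perms, 1, function(p) stats::cor(rx[p], ry))
  list(rho = rho_obs, p = mean(abs(rho_all) >= abs(rho_obs) - 1e-9))
}

permutations_oracle <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_oracle(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# noiseless / noise-controlled synthetic config used by fitting tests
quiet_config <- function(seed, tau_stim, tau_rec, noise_sd = 0,
                         severe_s = 1800) {
  synthetic_config(
    seed = seed, tau_stim = tau_stim, tau_rec = tau_rec,
    osc_amp_ms = c(BASELINE = 0, MILD = 0, MODERATE = 0, SEVERE = 0, RECOVERY = 0),
    noise_sd_ms = c(BASELINE = noise_sd, MILD = noise_sd, MODERATE = noise_sd,
                    SEVERE = noise_sd, RECOVERY = noise_sd),
    artifact_rate_per_h = 0,
    phase_durations_s = c(BASELINE = 300, MILD = 300, MODERATE = 300,
                          SEVERE = severe_s, RECOVERY = 300)
  )
}
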