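test_that("Spearman correlation handles monotone and tied data", {
  expect_equal(spearman_cor(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_cor(1:4, c(40, 30, 20, 10))$rho, -1)
  # invariance under strictly monotone transforms
  set.seed(3)
  x <- stats::rnorm(12); y <- stats::rnorm(12)
  r0 <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(exp(x), y)$rho, r0)
  expect_equal(spearman_cor(x, y^3 + 5 * y)$rho, r0)
  expect_error(spearman_cor(rep(1, 5), 1:5), "zero variance")
})

test_that("exact Spearman p equals full enumeration, ties included", {
  cases <- list(
    list(x = c(1, 2, 2, 3), y = c(4, 3, 5, 1)),
    list(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3)),
    list(x = c(5, 1, 1, 3, 2), y = c(2, 2, 4, 1, 5))
  )
  for (cs in cases) {
    got <- spearman_cor(cs$x, cs$y)
    orc <- spearman_enum_oracle(cs$x, cs$y)
    expect_true(got$exact)
    expect_equal(got$rho, orc$rho, tolerance = 1e-12)
    expect_equal(got$p, orc$p, tolerance = 1e-12)
  }
  # untied case cross-checked against the standard implementation
  set.seed(1)
  x <- stats::rnorm(8); y <- stats::rnorm(8)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = TRUE))
  got <- spearman_cor(x, y)
  expect_equal(got$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-9)
})

test_that("large-sample Spearman p uses the t approximation", {
  set.seed(2)
  x <- stats::rnorm(28); y <- x + stats::rnorm(28, sd = 2)
  got <- spearman_cor(x, y)
  expect_false(got$exact)
  tstat <- got$rho * sqrt(26 / (1 - got$rho^2))
  expect_equal(got$p, 2 * stats::pt(-abs(tstat), df = 26), tolerance = 1e-12)
})

test_that("exact Wilcoxon matches sign-flip enumeration, ties included", {
  # seven all-positive differences: only 2 of 2^7 assignments are as extreme
  res <- wilcoxon_signed_rank(2:8, 1:7)
  expect_true(res$exact)
  expect_equal(res$p, 2 / 128)
  expect_equal(res$p, wilcoxon_enum_oracle(2:8, 1:7))

  # perfectly balanced alternating differences: p = 1 under the exact null
  a <- c(10, 20, 30, 40, 50, 60)
  b <- a + c(1, -1, 1, -1, 1, -1)
  expect_equal(wilcoxon_signed_rank(a, b)$p, 1)

  set.seed(14)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    x <- sample(1:6, n, replace = TRUE)   # forces tied |differences|
    y <- sample(1:6, n, replace = TRUE)
    if (sum(x != y) < 5) next
    expect_equal(wilcoxon_signed_rank(x, y)$p, wilcoxon_enum_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank(1:6, 1:6), "all paired differences")
})

test_that("exact Wilcoxon agrees with the standard implementation when untied", {
  set.seed(15)
  for (i in 1:5) {
    x <- stats::rnorm(12); y <- stats::rnorm(12)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  # beyond the exact limit the normal approximation is used
  x <- stats::rnorm(40); y <- x + stats::rnorm(40, sd = 0.5)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_false(ours$exact)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
})

test_that("significant T-ranges are maximal runs of corrected p < alpha", {
  allp <- rep(0.001, 50)
  r <- significant_T_ranges(allp)
  expect_equal(r, data.frame(T_from = 1L, T_to = 50L))

  p <- rep(0.5, 50); p[2:5] <- 0.01   # corrected 0.03 < 0.05
  r2 <- significant_T_ranges(p)
  expect_equal(r2, data.frame(T_from = 2L, T_to = 5L))

  # Bonferroni can push a raw-significant p over alpha
  p3 <- rep(0.5, 50); p3[10] <- 0.03  # corrected 0.09
  expect_equal(nrow(significant_T_ranges(p3)), 0L)

  set.seed(6)
  p4 <- stats::runif(50, 0, 0.1)
  got <- significant_T_ranges(p4)
  sig <- pmin(1, 3 * p4) < 0.05
  # scan oracle: every reported range is significant throughout and maximal
  for (k in seq_len(nrow(got))) {
    expect_true(all(sig[got$T_from[k]:got$T_to[k]]))
    if (got$T_from[k] > 1) expect_false(sig[got$T_from[k] - 1])
    if (got$T_to[k] < 50) expect_false(sig[got$T_to[k] + 1])
  }
  expect_equal(sum(got$T_to - got$T_from + 1), sum(sig))
})

test_that("quartile summaries use linear interpolation and match an oracle", {
  expect_equal(quartile_summary(5), c(median = 5, q1 = 5, q3 = 5, mean = 5))
  set.seed(20)
  v <- stats::rnorm(10)
  q <- quartile_summary(v)
  s <- sort(v)
  lin <- function(p) {
    h <- 1 + p * (length(s) - 1)
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
  }
  expect_equal(unname(q["q1"]), lin(0.25), tolerance = 1e-12)
  expect_equal(unname(q["median"]), lin(0.5), tolerance = 1e-12)
  expect_equal(unname(q["q3"]), lin(0.75), tolerance = 1e-12)
})

test_that("SDNN uses original beats only and the n-1 denominator", {
  expect_equal(sdnn(make_series(rep(500, 30))), 0)
  expect_equal(sdnn(make_series(c(390, 410))), sqrt(2 * 10^2 / 1), tolerance = 1e-9)
  set.seed(21)
  rr <- 400 + stats::rnorm(200, sd = 12)
  ser <- make_series(rr)
  two_pass <- sqrt(sum((rr - mean(rr))^2) / (length(rr) - 1))
  expect_equal(sdnn(ser), two_pass, tolerance = 1e-12)
  # reconstructed beats are excluded; windows restrict the sample
  prov <- rep("original", 200); prov[50:60] <- "reconstructed"
  elig <- rep(TRUE, 200); elig[50:60] <- FALSE
  ser2 <- make_series(rr, provenance = prov, eligible = elig)
  rr_orig <- rr[prov == "original"]
  expect_equal(sdnn(ser2), stats::sd(rr_orig), tolerance = 1e-12)
  expect_error(sdnn(make_series(c(400, 400),
                                provenance = c("original", "reconstructed"),
                                eligible = c(TRUE, FALSE))),
               "at least 2")
})
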