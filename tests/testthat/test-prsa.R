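# Alternating series a +/- b: every interior beat with rr = a + b is a
# deceleration anchor at T = 1, and DC = b in closed form.
test_that("alternating series reproduces the T = s = 1 closed form", {
  a <- 400; b <- 10
  rr <- rep(c(a - b, a + b), 60)
  ser <- make_series(rr, eligible = rep(TRUE, length(rr)))
  L <- 5L
  dec <- select_anchor_points(ser, T = 1, mode = "deceleration", L = L)
  oracle <- prsa_oracle(ser, T = 1, s = 1, L = L, mode = "deceleration")
  expect_identical(dec, oracle$anchors)
  expect_true(all(rr[dec] == a + b))

  curve <- compute_prsa_curve(ser, dec, L = L)
  expect_equal(unname(curve$values[as.character(0)]), a + b)
  expect_equal(unname(curve$values[as.character(-1)]), a - b)
  expect_equal(unname(curve$values[as.character(1)]), a - b)
  expect_equal(compute_capacity(curve, s = 1), b)   # ((a+b)-(a-b))/2

  acc <- select_anchor_points(ser, T = 1, mode = "acceleration", L = L)
  curve_a <- compute_prsa_curve(ser, acc, L = L)
  expect_equal(abs(compute_capacity(curve_a, s = 1)), b)
})

test_that("degenerate inputs yield no anchors or clear errors", {
  const <- make_series(rep(400, 200), eligible = rep(TRUE, 200))
  expect_length(select_anchor_points(const, T = 3, mode = "deceleration", L = 10), 0)
  expect_length(select_anchor_points(const, T = 3, mode = "acceleration", L = 10), 0)

  none <- make_series(rep(c(390, 410), 50), eligible = rep(FALSE, 100))
  expect_length(select_anchor_points(none, T = 1, mode = "deceleration", L = 5), 0)
  expect_error(compute_prsa_curve(none, integer(0), L = 5), "no anchor")
  expect_error(select_anchor_points(make_series(rep(400, 20)), T = 1,
                                    mode = "deceleration", L = 10),
               "too short")
})

test_that("a single anchor's curve is its window verbatim", {
  set.seed(4)
  rr <- 400 + stats::rnorm(60, sd = 20)
  ser <- make_series(rr)
  L <- 8L
  curve <- compute_prsa_curve(ser, 30L, L = L)
  expect_equal(unname(curve$values), rr[(30 - L):(30 + L - 1)])
})

test_that("the s = 2 capacity reduces to the adult four-sample formula", {
  set.seed(5)
  rr <- 420 + stats::rnorm(400, sd = 25)
  ser <- mark_anchor_exclusions(make_series(rr))
  anchors <- select_anchor_points(ser, T = 2, mode = "deceleration", L = 10)
  curve <- compute_prsa_curve(ser, anchors, L = 10)
  X <- curve$values
  four <- (X[["0"]] + X[["1"]] - X[["-1"]] - X[["-2"]]) / 4
  expect_equal(compute_capacity(curve, s = 2), four, tolerance = 1e-14)
})

test_that("streaming AC/DC equals the materialize-all-windows oracle", {
  set.seed(202)
  for (rep_i in 1:25) {
    n <- 400
    rr <- 400 + stats::rnorm(n, sd = 30)
    elig <- stats::runif(n) > 0.15
    ser <- make_series(rr, eligible = elig)
    T <- sample(1:8, 1); L <- sample(max(T, 4):12, 1); s <- sample(seq_len(min(T + 2, L)), 1)
    for (mode in c("deceleration", "acceleration")) {
      anchors <- select_anchor_points(ser, T = T, mode = mode, L = L)
      orc <- prsa_oracle(ser, T = T, s = s, L = L, mode = mode)
      expect_identical(anchors, orc$anchors)
      if (length(anchors) > 0) {
        cap <- compute_capacity(compute_prsa_curve(ser, anchors, L = L), s = s)
        expect_equal(cap, orc$capacity, tolerance = 1e-12)
      }
    }
  }
})

test_that("capacity is offset-invariant and scale-equivariant", {
  set.seed(7)
  rr <- 400 + stats::rnorm(500, sd = 20)
  ser <- make_series(rr, eligible = rep(TRUE, 500))
  cap_of <- function(x, T, s, L, mode) {
    a <- select_anchor_points(x, T = T, mode = mode, L = L)
    compute_capacity(compute_prsa_curve(x, a, L = L), s = s)
  }
  for (mode in c("deceleration", "acceleration")) {
    base <- cap_of(ser, 3, 3, 10, mode)
    shifted <- make_series(rr + 120, eligible = rep(TRUE, 500))
    expect_equal(cap_of(shifted, 3, 3, 10, mode), base, tolerance = 1e-12)
    scaled <- make_series(rr * 1.7, eligible = rep(TRUE, 500))
    expect_equal(cap_of(scaled, 3, 3, 10, mode), 1.7 * base, tolerance = 1e-12)
  }
})

test_that("time reversal swaps AC and DC exactly", {
  set.seed(8)
  rr <- 400 + stats::rnorm(301, sd = 15)
  fwd <- make_series(rr, eligible = rep(TRUE, 301))
  rev_ <- make_series(rev(rr), eligible = rep(TRUE, 301))
  for (T in c(1, 2, 5)) {
    s <- T; L <- 10
    acc <- select_anchor_points(fwd, T = T, mode = "acceleration", L = L)
    dec_r <- select_anchor_points(rev_, T = T, mode = "deceleration", L = L)
    expect_equal(sort(303 - acc), sort(dec_r))  # anchor index duality j = n+2-i
    ac <- compute_capacity(compute_prsa_curve(fwd, acc, L = L), s = s)
    dc_r <- compute_capacity(compute_prsa_curve(rev_, dec_r, L = L), s = s)
    expect_equal(dc_r, -ac, tolerance = 1e-12)
  }
})

test_that("anchors never span concatenation junctions unless allowed", {
  set.seed(10)
  rr <- 400 + stats::rnorm(200, sd = 20)
  seg <- rep(1:2, each = 100)
  ser <- make_series(rr, eligible = rep(TRUE, 200), segment = seg)
  anchors <- select_anchor_points(ser, T = 2, mode = "deceleration", L = 10)
  expect_true(all(seg[anchors - 10] == seg[anchors + 9]))
  loose <- select_anchor_points(ser, T = 2, mode = "deceleration", L = 10,
                                allow_cross_boundary = TRUE)
  expect_gt(length(loose), length(anchors))
})

test_that("the capacity spectrum is consistent with single-T calls and flags", {
  set.seed(12)
  rr <- 400 + stats::rnorm(700, sd = 25)
  ser <- mark_anchor_exclusions(make_series(rr))
  spec <- capacity_spectrum(ser, T_values = 1:20, L = 25, min_anchors = 150)
  expect_equal(nrow(spec), 20L)
  for (T in c(1, 7, 20)) {
    anchors <- select_anchor_points(ser, T = T, mode = "deceleration", L = 25)
    cap <- compute_capacity(compute_prsa_curve(ser, anchors, L = 25), s = T)
    row <- spec[spec$T == T, ]
    expect_equal(row$DC_abs_ms, abs(cap), tolerance = 1e-12)
    expect_equal(row$n_anchors_dec, length(anchors))
  }
  short <- mark_anchor_exclusions(make_series(400 + stats::rnorm(150, sd = 25)))
  spec2 <- capacity_spectrum(short, T_values = 5, L = 25, min_anchors = 150)
  expect_true(spec2$unreliable_dec)   # ~50 usable positions at most
  expect_false(is.na(spec2$DC_abs_ms))
})

test_that("the anchor filter cutoff follows 1/(2 T rr)", {
  expect_equal(t_to_cutoff_frequency(1, 0.4), 1.25)
  expect_equal(t_to_cutoff_frequency(4, 0.4), 0.3125)
  expect_equal(t_to_cutoff_frequency(10, 0.4), t_to_cutoff_frequency(5, 0.4) / 2)
})
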