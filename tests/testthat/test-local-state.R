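test_that("variant presets reproduce the published settings table", {
  v <- lapply(0:7, inclination_config)
  expect_equal(vapply(v, `[[`, integer(1), "m"),
               c(3L, 3L, 3L, 3L, 3L, 3L, 4L, 3L))
  expect_identical(vapply(v, `[[`, character(1), "delta_scheme"),
                   c("difference", "integral_ratio", "difference", "slope",
                     "slope", "sign", "sign", "sign"))
  expect_identical(vapply(v, `[[`, character(1), "weight_scheme"),
                   c("constant_one", "constant_one", "binary_norm_thr",
                     "binary_norm_thr", "linear_min_max", "linear_min_max",
                     "linear_min_max", "linear_low_high"))
  cfg <- inclination_config(7)
  expect_equal(cfg$delta_band, 0.1)
  expect_equal(cfg$r_minus, 0.5)
  expect_equal(cfg$m_minus, 3L)
  expect_equal(cfg$m_plus, 3L)
  expect_equal(cfg$power_iterations, 10000L)
  expect_error(inclination_config(8), "0..7")
  expect_error(inclination_config(7, r_minus = 1.5), "r_minus")
  expect_error(inclination_config(7, m_minus = 5), "critical levels")
})

test_that("pair deltas measure difference, sign, slope, and area fraction", {
  expect_equal(pair_delta(series_of(c(125, 120)), 1, "difference"), -5)
  expect_equal(pair_delta(series_of(c(120, 120)), 1, "sign"), 0)
  s <- biomarker_series("sBP", c(0, 5), c(100, 110))
  expect_equal(pair_delta(s, 1, "slope"), 2)
  # integral-ratio contributions are signed area fractions summing to <= 1
  set.seed(7)
  r <- series_of(runif(9, 80, 160), times = cumsum(runif(9, 1, 200)))
  fr <- vapply(1:8, function(i) pair_delta(r, i, "integral_ratio"),
               numeric(1))
  expect_equal(sum(abs(fr)), 1, tolerance = 1e-12)
  expect_error(pair_delta(r, 9, "difference"), "out of range")
})

test_that("weights amplify clinically alarming moves within [1, 2]", {
  sbp <- sbp_spec()
  # rise below normality is benign
  expect_equal(pair_weight(110, +1, sbp, "binary_norm_thr"), 1)
  # rise above normality is alarming
  expect_equal(pair_weight(130, +1, sbp, "binary_norm_thr"), 2)
  # fall above normality: not yet an improvement into range
  expect_equal(pair_weight(130, -1, sbp, "binary_norm_thr"), 1)
  # fall below normality: consolidating a good value
  expect_equal(pair_weight(110, -1, sbp, "binary_norm_thr"), 2)
  # linear scale over [low, high]: endpoint and midpoint
  expect_equal(pair_weight(160, +1, sbp, "linear_low_high"), 2)
  expect_equal(pair_weight(115, +1, sbp, "linear_low_high"), 1.5)
  expect_equal(pair_weight(115, -1, sbp, "linear_low_high"), 1.5)
  # no change, or the unweighted scheme, always 1
  expect_equal(pair_weight(200, 0, sbp, "linear_low_high"), 1)
  expect_equal(pair_weight(200, +1, sbp, "constant_one"), 1)
  # property: any scheme, any value/sign stays in [1, 2]
  set.seed(11)
  for (scheme in c("binary_norm_thr", "linear_min_max", "linear_low_high")) {
    w <- vapply(runif(200, 0, 300), function(v) {
      pair_weight(v, sample(c(-1L, 1L), 1), sbp, scheme)
    }, numeric(1))
    expect_true(all(w >= 1 & w <= 2), label = scheme)
  }
})

test_that("HDL weights mirror the decrease-good rules", {
  hdl <- hdl_spec()
  # an HDL increase at the top of the acceptable range is maximally good
  expect_equal(pair_weight(2, +1, hdl, "linear_low_high"), 2)
  # an HDL decrease at the bottom is maximally alarming
  expect_equal(pair_weight(1, -1, hdl, "linear_low_high"), 2)
  # binary: a fall while already below normality is alarming
  expect_equal(pair_weight(1.2, -1, hdl, "binary_norm_thr"), 2)
  expect_equal(pair_weight(1.8, +1, hdl, "binary_norm_thr"), 2)
  expect_equal(pair_weight(1.8, -1, hdl, "binary_norm_thr"), 1)
})

test_that("original-variant window scores telescope exactly", {
  cfg0 <- inclination_config(0)
  s <- series_of(c(130, 125, 120))
  expect_equal(window_score(s, 3, sbp_spec(), cfg0), -10)
  set.seed(3)
  for (rep in 1:1000) {
    n <- sample(3:12, 1)
    s <- series_of(rnorm(n, 130, 20), times = cumsum(runif(n, 1, 300)))
    k <- sample(seq_len(n - 2), 1) + 2L
    expect_equal(window_score(s, k, sbp_spec(), cfg0),
                 s$value[k] - s$value[k - 2])
  }
})

test_that("window scores respond to clinical weighting", {
  cfg7 <- inclination_config(7)
  s <- series_of(c(150, 155, 158))
  w1 <- pair_weight(155, +1, sbp_spec(), "linear_low_high")
  w2 <- pair_weight(158, +1, sbp_spec(), "linear_low_high")
  expect_equal(window_score(s, 3, sbp_spec(), cfg7), w1 + w2)
  expect_gt(window_score(s, 3, sbp_spec(), cfg7), 0)
  # constant window scores zero under every variant
  flat <- series_of(rep(120, 5))
  for (v in 0:7) {
    cfg <- inclination_config(v)
    expect_equal(window_score(flat, cfg$m, sbp_spec(), cfg), 0)
  }
})

test_that("local-state counts follow the sliding-window arithmetic", {
  s <- series_of(rnorm(9, 120, 10))
  expect_length(local_states(s, sbp_spec(), inclination_config(5)), 7L)
  expect_length(local_states(s, sbp_spec(), inclination_config(6)), 6L)
  short <- series_of(rnorm(3))
  expect_error(local_states(short, sbp_spec(), inclination_config(6)),
               "shorter")
})

test_that("monotone improvement yields all-survival states and vice versa", {
  cfg0 <- inclination_config(0)
  down <- series_of(seq(160, 120, length.out = 9))
  expect_true(all(local_states(down, sbp_spec(), cfg0) == 0L))
  up <- series_of(seq(120, 160, length.out = 9))
  expect_true(all(local_states(up, sbp_spec(), cfg0) == 1L))
  # for HDL the mirror makes an increase the improving direction
  hdl_up <- series_of(seq(1, 2, length.out = 9), biomarker = "HDL")
  expect_true(all(local_states(hdl_up, hdl_spec(), inclination_config(7)) == 0L))
})

test_that("negating deviations around a constant flips nonzero states", {
  set.seed(5)
  for (scheme in c("difference", "slope", "sign")) {
    cfg <- inclination_config(version = NULL, m = 3, delta_scheme = scheme,
                              weight_scheme = "constant_one")
    dev <- rnorm(9, 0, 15)
    t <- cumsum(runif(9, 1, 200))
    a <- series_of(120 + dev, times = t)
    b <- series_of(120 - dev, times = t)
    sa <- local_states(a, sbp_spec(), cfg)
    sb <- local_states(b, sbp_spec(), cfg)
    nz <- attr(sa, "scores") != 0
    expect_true(all(sa[nz] != sb[nz]), label = scheme)
  }
})
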