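test_that("transition matrix encodes shift dynamics and critical levels", {
  # m = 1: both singleton sequences are absorbing, Z is the identity
  tm1 <- transition_model(inclination_config(version = NULL, m = 1,
    delta_scheme = "sign", weight_scheme = "constant_one"))
  expect_equal(tm1$Z, diag(2), ignore_attr = TRUE)
  # m = 3 defaults: the all-collapse row is a self-loop
  tm3 <- transition_model(inclination_config(7))
  expect_equal(unname(tm3$Z["---", "---"]), 1)
  expect_equal(unname(tm3$Z["+++", "+++"]), 1)
  # m = 2 defaults: an unstable sequence splits evenly over its shifts
  tm2 <- transition_model(config_m2())
  expect_equal(unname(tm2$Z["-+", c("+-", "++")]), c(0.5, 0.5))
  expect_equal(sum(tm2$Z["-+", ]), 1)
  # every row of Z and Z_inf is stochastic
  for (tm in list(tm1, tm2, tm3)) {
    expect_equal(rowSums(tm$Z), rep(1, 2^tm$m), ignore_attr = TRUE,
                 tolerance = 1e-9)
    expect_equal(rowSums(tm$Z_inf), rep(1, 2^tm$m), ignore_attr = TRUE,
                 tolerance = 1e-9)
  }
})

test_that("limiting matrix equals the linear-system absorption oracle", {
  for (m in 2:5) {
    tm <- transition_model(inclination_config(version = NULL, m = m,
      delta_scheme = "sign", weight_scheme = "constant_one"))
    expect_equal(tm$Z_inf, absorption_oracle(tm$Z), tolerance = 1e-9)
    # limiting mass sits only on the two absorbing sequences
    interior <- tm$Z_inf[, -c(1, 2^m), drop = FALSE]
    expect_lt(max(abs(interior)), 1e-6)
  }
  # identity stays the identity under any power
  expect_equal(limiting_matrix(diag(4), 12345), diag(4))
})

test_that("absorption probability from the alternating sequence is 1/3", {
  tm <- transition_model(config_m2())
  expect_equal(unname(tm$Z_inf["-+", "--"]), 1 / 3, tolerance = 1e-9)
  expect_equal(unname(tm$Z_inf["+-", "--"]), 2 / 3, tolerance = 1e-9)
  d <- rep(0, 4); d[3] <- 1  # point mass on (-, +)
  expect_equal(final_state_probability(tm$Z_inf, d, 4), 1 / 3,
               tolerance = 1e-9)
})

test_that("sequence distribution counts overlapping windows", {
  expect_equal(unname(sequence_distribution(rep(1L, 7), 3)),
               c(rep(0, 7), 1))
  q <- sequence_distribution(c(1, 0, 1, 0, 1, 0), 2)
  expect_equal(unname(q[c("-+", "+-")]), c(3 / 5, 2 / 5))
  # 7 states, m = 3: five subsequences, so masses are fifths
  q3 <- sequence_distribution(c(1, 1, 0, 1, 0, 0, 1), 3)
  expect_equal(sum(q3), 1)
  expect_true(all(q3 * 5 == round(q3 * 5)))
  expect_error(sequence_distribution(c(1, 0), 3), "shorter")
})

test_that("uniform prior gives collapse probability one half for m = 1..5", {
  for (m in 1:5) {
    tm <- transition_model(inclination_config(version = NULL, m = m,
      delta_scheme = "sign", weight_scheme = "constant_one"))
    u <- rep(1 / 2^m, 2^m)
    expect_equal(final_state_probability(tm$Z_inf, u, 2^m), 0.5,
                 tolerance = 1e-9)
  }
})

test_that("index is bounded by 2 and monotone in planted collapse mass", {
  tm <- transition_model(inclination_config(7))
  u <- rep(1 / 8, 8)
  p_minus <- final_state_probability(tm$Z_inf, u, 8)
  # point mass on all-collapse maximizes the index at 2
  point <- c(rep(0, 7), 1)
  expect_equal(final_state_probability(tm$Z_inf, point, 8) / p_minus, 2)
  # moving mass from all-survival to all-collapse never decreases the index
  set.seed(9)
  base <- runif(8); base <- base / sum(base)
  idx <- vapply(seq(0, base[1], length.out = 11), function(shift) {
    q <- base; q[1] <- q[1] - shift; q[8] <- q[8] + shift
    final_state_probability(tm$Z_inf, q, 8) / p_minus
  }, numeric(1))
  expect_true(all(diff(idx) >= -1e-12))
})

test_that("banded decision rule applies strict cuts and half-series tie-break", {
  st <- c(1L, 0L, 1L, 0L, 1L)
  expect_equal(decide_final_state(1.2, st, 0.1),
               list(decision = "collapse", tie_break_used = FALSE))
  expect_equal(decide_final_state(0.5, st, 0.1),
               list(decision = "survival", tie_break_used = FALSE))
  # inside the band: compare collapse share across halves, middle dropped
  tb <- decide_final_state(1.0, c(0L, 0L, 0L, 1L, 1L, 1L, 1L), 0.1)
  expect_equal(tb, list(decision = "collapse", tie_break_used = TRUE))
  # equal shares decide survival
  eq <- decide_final_state(1.05, c(1L, 0L, 1L, 0L), 0.1)
  expect_equal(eq, list(decision = "survival", tie_break_used = TRUE))
  # band edges are inclusive (strict inequalities outside)
  expect_true(decide_final_state(1.1, c(0L, 0L), 0.1)$tie_break_used)
  expect_true(decide_final_state(0.9, c(0L, 0L), 0.1)$tie_break_used)
})

test_that("full fit classifies unambiguous trajectories", {
  sbp <- sbp_spec()
  up <- series_of(c(165, 172, 180, 190, 199), times = c(0, 80, 200, 330, 400))
  fit <- inclination(up, sbp)
  expect_s3_class(fit, "inclination")
  expect_identical(fit$decision, "collapse")
  expect_equal(fit$index, 2)
  expect_false(fit$tie_break_used)
  down <- series_of(c(199, 190, 180, 172, 125), times = c(0, 80, 200, 330, 400))
  fit2 <- inclination(down, sbp)
  expect_identical(fit2$decision, "survival")
  expect_equal(fit2$index, 0)
  # a flat series maps zero scores to collapse states, hence collapse
  flat <- series_of(rep(120, 5))
  expect_identical(inclination(flat, sbp)$decision, "collapse")
  # eligibility is enforced on original readings
  expect_error(inclination(series_of(c(1, 2, 3, 4)), sbp), "at least 5")
})

test_that("fits are deterministic and internally consistent", {
  set.seed(21)
  s <- series_of(rnorm(6, 130, 12), times = cumsum(runif(6, 20, 250)))
  f1 <- inclination(s, sbp_spec())
  f2 <- inclination(s, sbp_spec())
  expect_identical(coef(f1), coef(f2))
  expect_equal(sum(f1$q_c), 1)
  expect_true(all(f1$q_c >= 0))
  expect_equal(f1$index, f1$P_c_minus / f1$P_minus)
  expect_gte(f1$index, 0)
  expect_lte(f1$index, 2 + 1e-12)
  expect_length(f1$states, length(f1$oversampled$value) - f1$config$m + 1)
})
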