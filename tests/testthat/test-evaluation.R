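test_that("resampling interpolates linearly and crosses the seam correctly", {
  a <- trajectory(c(0, 1), c(0, 4.8))
  expect_equal(resample(a, 0.5), 2.4)

  seam <- trajectory(c(0, 1), c(179, -179))   # clockwise through the seam
  expect_equal(resample(seam, 0.5), -180)

  expect_error(resample(a, 1.5), class = "gantrycam_range_error")
})

test_that("circular deviation matches the brute-force oracle and is metric", {
  expect_equal(circular_deviation(10, 10), 0)
  expect_equal(circular_deviation(179, -179), 2)

  set.seed(71)
  for (i in 1:500) {
    ab <- runif(2, -540, 540)
    expect_equal(circular_deviation(ab[1], ab[2]),
                 circ_dev_oracle(ab[1], ab[2]), tolerance = 1e-10)
  }
  # symmetry and the triangle inequality on the circle
  for (i in 1:200) {
    abc <- runif(3, -180, 180)
    expect_equal(circular_deviation(abc[1], abc[2]),
                 circular_deviation(abc[2], abc[1]))
    expect_lte(circular_deviation(abc[1], abc[3]),
               circular_deviation(abc[1], abc[2]) +
                 circular_deviation(abc[2], abc[3]) + 1e-12)
  }
})

test_that("planted time offsets are recovered to within one grid step", {
  # delayed copy of a simple motion
  t <- seq(0, 20, by = 1 / 30)
  a <- trajectory(t, wrap_deg_180(3 * t), rate_hz = 30)
  b <- trajectory(t, wrap_deg_180(3 * pmax(t - 0.150, 0)), rate_hz = 30)
  expect_lt(abs(estimate_time_offset(a, b, search_s = 0.5) - 0.150), 0.0015)

  expect_equal(estimate_time_offset(a, a, search_s = 0.2), 0)

  # offsets beyond the window saturate at the boundary, with a warning
  c_ <- trajectory(t, wrap_deg_180(3 * pmax(t - 0.9, 0)), rate_hz = 30)
  expect_warning(s <- estimate_time_offset(a, c_, search_s = 0.5), "boundary")
  expect_equal(abs(s), 0.5)

  # all three QA plan shapes, subsampled truth, planted 0.13 s shift
  for (plan in list(constant_speed_plan(direction = "CW"),
                    speed_transition_plan(direction = "CCW"),
                    maio_plan(direction = "CW"))) {
    tr <- plan_to_trajectory(plan, dt_s = 0.05)
    shifted <- trajectory(tr$time_s + 0.13, tr$gantry_deg,
                          rate_hz = attr(tr, "rate_hz"))
    # shifted(t) = tr(t - 0.13), so shifted(t + 0.13) aligns with tr(t)
    est <- estimate_time_offset(tr, shifted, search_s = 0.3, step_s = 0.001)
    expect_lt(abs(est - 0.13), 0.0015, label = attr(plan, "kind"))
  }
})

test_that("comparison statistics are exact for constructed deviations", {
  t <- seq(0, 10, by = 0.1)
  a <- trajectory(t, wrap_deg_180(5 * t), rate_hz = 10, source = "double_dot")

  self <- compare_trajectories(a, a)
  expect_equal(self$stats$mean_abs_dev_deg, 0)
  expect_equal(self$stats$sd_dev_deg, 0)
  expect_equal(self$stats$max_abs_dev_deg, 0)

  b <- trajectory(t, wrap_deg_180(5 * t + 0.5), rate_hz = 10, source = "dynalog")
  cmp <- compare_trajectories(a, b)
  expect_equal(cmp$stats$mean_abs_dev_deg, 0.5, tolerance = 1e-9)
  expect_equal(cmp$stats$sd_dev_deg, 0, tolerance = 1e-9)
  expect_equal(cmp$stats$max_abs_dev_deg, 0.5, tolerance = 1e-9)
  expect_equal(cmp$stats$pair_label, "double_dot-dynalog")

  expect_s3_class(tidy(cmp), "tbl_df")
  expect_equal(nrow(glance(cmp)), 1)
})

test_that("mean absolute deviation of Gaussian noise approaches sigma*sqrt(2/pi)", {
  sigma <- 0.3
  half_normal_mean <- sigma * sqrt(2 / pi)
  half_normal_sd <- sigma * sqrt(1 - 2 / pi)

  set.seed(81)
  for (n in c(2000, 100000)) {
    t <- seq_len(n) / 100
    a <- trajectory(t, rep(0, n))
    b <- trajectory(t, rnorm(n, sd = sigma))
    cmp <- compare_trajectories(a, b)
    se <- half_normal_sd / sqrt(n)
    expect_lt(abs(cmp$stats$mean_abs_dev_deg - half_normal_mean), 3 * se)
  }
})

test_that("static lead-ins can be excluded from the statistics", {
  t <- seq(0, 20, by = 1 / 30)
  ang <- ifelse(t < 12, 0, 4 * (t - 12))
  a <- trajectory(t, wrap_deg_180(ang), rate_hz = 30, source = "double_dot")
  # reference with an error only during the static part
  b <- trajectory(t, wrap_deg_180(ang + ifelse(t < 11, 1, 0)),
                  rate_hz = 30, source = "dynalog")
  with_static <- compare_trajectories(a, b)
  without <- compare_trajectories(a, b, exclude_static = TRUE)
  expect_gt(with_static$stats$mean_abs_dev_deg, 0.4)
  expect_lt(without$stats$mean_abs_dev_deg, 0.05)
  expect_true(all(without$deviations$time_s >= 11.9))
})
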