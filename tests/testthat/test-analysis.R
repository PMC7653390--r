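test_that("instantaneous speeds follow the frame-difference definition", {
  # stationary agent: all speeds zero
  still <- generate_fixture("constant_velocity", speed = 0, fps = 25, duration = 1)
  expect_true(all(instantaneous_speeds(still, 0.04)$speeds == 0))

  # 3-4-5 triangle: per-frame displacement (0.03, 0.04) m at 0.04 s -> 1.25 m/s
  tri <- data.frame(timeStep = 1:3, x = c(0, 0.03, 0.06), y = c(0, 0.04, 0.08))
  expect_equal(instantaneous_speeds(tri, 0.04)$speeds, c(1.25, 1.25),
               tolerance = 1e-12)

  # constant 1.5 m/s sampled at 25 fps recovers 1.5 everywhere
  cv <- generate_fixture("constant_velocity", speed = 1.5, fps = 25, duration = 2)
  v <- instantaneous_speeds(cv, 1 / 25)$speeds
  expect_equal(v, rep(1.5, 49), tolerance = 1e-12)

  # non-uniform frame spacing is an explicit error
  bad <- data.frame(timeStep = c(1, 2, 4), x = 0:2, y = 0)
  expect_error(instantaneous_speeds(bad, 0.04), "non-uniform")
})

test_that("mean speed averages the masked frames and rejects empty masks", {
  s <- structure(list(agent_id = 1, frame_interval = 0.04,
                      speeds = c(1, 2, 3), frames = 2:4),
                 class = "ccoop_speed_series")
  expect_equal(mean_speed(s), 2)
  expect_equal(mean_speed(s, c(TRUE, TRUE, FALSE)), 1.5)
  expect_error(mean_speed(s, c(FALSE, FALSE, FALSE)), "empty")

  set.seed(2)
  v <- runif(50)
  s2 <- structure(list(agent_id = 1, frame_interval = 0.04, speeds = v,
                       frames = 2:51), class = "ccoop_speed_series")
  m <- rep(c(TRUE, FALSE), 25)
  expect_equal(mean_speed(s2, m), sum(v[m]) / sum(m), tolerance = 1e-12)
})

test_that("inside/outside masks match brute-force containment", {
  area <- region_rect(1.0, 2.3, 2.55, 4.0)
  # trajectory entirely below both regions: both masks empty
  low <- data.frame(timeStep = 1:5, x = 1.7, y = seq(0.0, 0.1, length.out = 5))
  m <- split_inside_outside(low, area)
  expect_false(any(m$inside))
  expect_false(any(m$outside))

  # vertical crossing: inside frames are exactly those with y in the area span
  cross <- data.frame(timeStep = 1:200, x = 1.7, y = seq(0, 5, length.out = 200))
  m <- split_inside_outside(cross, area)
  expect_identical(m$inside, cross$y >= 2.3 & cross$y <= 4.0)
  # outside region: same width, 1.5 m window ending 0.6 m before the entrance
  expect_identical(m$outside, cross$y >= 0.2 & cross$y <= 1.7)

  # a frame exactly on the boundary is inside (closed-set convention)
  edge <- data.frame(timeStep = 1:2, x = c(1.7, 1.7), y = c(2.3, 4.0))
  expect_true(all(split_inside_outside(edge, area)$inside))
})

test_that("duration in area counts frames times the frame interval", {
  area <- region_rect(1.0, 2.3, 2.55, 4.0)
  never <- data.frame(timeStep = 1:10, x = 1.7, y = 0.1)
  expect_equal(duration_in_area(never, area, 0.04), 0)

  # 50 inside frames at 25 fps -> 2.0 s
  inside_y <- c(rep(0, 9), rep(3, 50), rep(5, 11))
  tr <- data.frame(timeStep = seq_along(inside_y), x = 1.7, y = inside_y)
  expect_equal(duration_in_area(tr, area, 0.04), 2.0)

  # straight crossing of 1.70 m at 0.70 m/s lasts 1.70/0.70 = 2.43 s
  fps <- 1000  # fine sampling so the frame count matches the continuous time
  tr2 <- generate_fixture("constant_velocity", speed = 0.70, fps = fps,
                          duration = 6, start = c(1.7, 2.3 - 0.7))
  d <- duration_in_area(tr2, area, 1 / fps)
  expect_equal(d, 1.70 / 0.70, tolerance = 2 / (fps * 2.43))
  expect_equal(round(d, 2), 2.43)
})

test_that("displacement metrics: end vs maximum excursion", {
  still <- generate_fixture("constant_velocity", speed = 0)
  ds <- displacement_stats(still)
  expect_equal(ds$end_displacement, 0)
  expect_equal(ds$max_displacement, 0)

  oab <- generate_fixture("out_and_back", amplitude = 0.5)
  ds <- displacement_stats(oab)
  expect_equal(ds$end_displacement, 0, tolerance = 1e-12)
  expect_equal(ds$max_displacement, 0.5, tolerance = 1e-12)

  # brute-force loop oracle on a random 100-frame walk
  rw <- generate_fixture("random_walk", fps = 25, duration = 4, seed = 9)
  ds <- displacement_stats(rw)
  dmax <- 0
  for (t in seq_len(nrow(rw))) {
    dmax <- max(dmax, sqrt((rw$x[t] - rw$x[1])^2 + (rw$y[t] - rw$y[1])^2))
  }
  dend <- sqrt((rw$x[100] - rw$x[1])^2 + (rw$y[100] - rw$y[1])^2)
  expect_equal(ds$max_displacement, dmax, tolerance = 1e-12)
  expect_equal(ds$end_displacement, dend, tolerance = 1e-12)
  expect_gte(ds$max_displacement, ds$end_displacement)
})

test_that("slow-down factor reproduces the printed arithmetic", {
  expect_equal(round(slowdown_factor(1.33, 0.70), 1), 1.9)
  expect_equal(slowdown_factor(1, 1), 1)
  expect_equal(slowdown_factor(2.0, 0.5), 4.0)
  expect_error(slowdown_factor(1.33, 0), "v_inside")
})

test_that("paired one-sided t-test matches the definition and textbook values", {
  # critical value at N = 30: lower 5% t quantile with 29 d.f. is -1.70
  set.seed(1)
  tt <- paired_onesided_ttest(runif(30), runif(30) + 1)
  expect_equal(round(tt$critical_value, 2), -1.70)
  expect_equal(tt$N, 30)

  # hand-computed case: d = (-0.5, -0.6, -0.7) -> T = sqrt(3)*(-0.6)/0.1
  tt2 <- paired_onesided_ttest(c(0.5, 0.4, 0.3), c(1.0, 1.0, 1.0))
  expect_equal(round(tt2$T, 2), -10.39)
  expect_true(tt2$reject_H0)

  # zero variance is an explicit precondition error
  expect_error(paired_onesided_ttest(c(1, 2, 3), c(1, 2, 3)), "variance")

  # agreement with the stats::t.test implementation on random inputs
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(3:40, 1)
    v_in <- rnorm(n, 0.7, 0.2)
    v_out <- rnorm(n, 1.3, 0.2)
    mine <- paired_onesided_ttest(v_in, v_out)
    ref <- stats::t.test(v_in, v_out, paired = TRUE, alternative = "less")
    expect_equal(mine$T, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("the KS survey retains good fits above the strict threshold only", {
  set.seed(123)
  x <- rnorm(5000, 10, 2)
  out <- ks_fit_survey(x, candidates = c("norm", "exp"))
  expect_identical(out$family, "norm")
  expect_gt(out$p_value[1], 0.90)

  # retention is strict: a family at exactly the threshold is excluded
  p_norm <- out$p_value[1]
  none <- ks_fit_survey(x, candidates = "norm", p_keep = p_norm)
  expect_equal(nrow(none), 0)

  # several candidates: results sorted by descending p-value
  set.seed(42)
  y <- rgamma(2000, shape = 3, rate = 2)
  multi <- ks_fit_survey(y, candidates = c("gamma", "weibull", "lnorm", "exp"),
                         p_keep = 0)
  expect_true(all(diff(multi$p_value) <= 0))
  expect_identical(multi$family[1], "gamma")

  expect_error(ks_fit_survey(x, candidates = character(0)), "non-empty")
  expect_error(ks_fit_survey(rnorm(5)), "at least 20")

  # an unfittable family is skipped with a warning, not fatal
  expect_warning(
    res <- ks_fit_survey(c(rnorm(100, 10, 1), -5), candidates = c("lnorm", "norm")),
    "failed to fit"
  )
  expect_false("lnorm" %in% res$family)
})
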