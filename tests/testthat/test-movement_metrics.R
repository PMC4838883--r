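t0 <- as.POSIXct("2009-09-05 00:00:00", tz = "UTC")

test_that("step displacement is distance over time over fork length", {
  a <- make_fixes("A", t0, 0, 0)
  b <- make_fixes("A", t0 + 60, 12.42, 0)
  expect_equal(step_displacement(a, b, fork_length = 300), 12.42 / 60 / 0.3,
               tolerance = 1e-12)  # 0.69 BLs^-1
  expect_equal(step_displacement(a, make_fixes("A", t0 + 60, 0, 0), 300), 0)
  expect_error(step_displacement(a, a, 300), "non-positive")

  # translation and rotation invariance
  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  p1 <- c(3, 4); p2 <- c(15.42, 4)
  q1 <- drop(R %*% p1) + c(100, -50); q2 <- drop(R %*% p2) + c(100, -50)
  d1 <- step_displacement(make_fixes("A", t0, p1[1], p1[2]),
                          make_fixes("A", t0 + 60, p2[1], p2[2]), 300)
  d2 <- step_displacement(make_fixes("A", t0, q1[1], q1[2]),
                          make_fixes("A", t0 + 60, q2[1], q2[2]), 300)
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("distance from the lake bed clamps small discordance", {
  lk <- flat_lake(depth = 10)
  expect_equal(dist_from_bed(make_fixes("A", t0, 50, 50, tag_depth = 5),
                             lk$bathy), 5)
  expect_equal(dist_from_bed(make_fixes("A", t0, 50, 50, tag_depth = 10),
                             lk$bathy), 0)
  expect_equal(dist_from_bed(make_fixes("A", t0, 50, 50, tag_depth = 10.1),
                             lk$bathy, tol = 0.25), 0)
  expect_error(dist_from_bed(make_fixes("A", t0, 50, 50, tag_depth = 12),
                             lk$bathy, tol = 0.25), "beyond tolerance")
})

test_that("daily summaries average steps onto the later fix's date", {
  lk <- flat_lake(depth = 10)
  fish <- fish_records("A", "Littoral", fork_length = 300, body_mass = 250,
                       tag_mass = 2.9)
  # constant-velocity fixes: 6 m per 80 min for 3 days
  n <- 54
  fx <- make_fixes("A", t0 + (0:(n - 1)) * 4800,
                   x = 10 + (0:(n - 1)) * 3, y = rep(50, n),
                   tag_depth = 4)
  ds <- daily_summaries(fx, fish, lk$bathy)
  expect_true(all(ds$mean_depth == 4))
  expect_true(all(ds$mean_dist_from_bed == 6))
  v <- 3 / 4800 / 0.3
  expect_true(all(abs(ds$mean_displacement - v) < 1e-9))
  expect_equal(sum(ds$n_steps), n - 1)

  # a single fix yields depth but no displacement
  one <- make_fixes("A", t0, 50, 50, tag_depth = 4)
  d1 <- daily_summaries(one, fish, lk$bathy)
  expect_equal(d1$n_steps, 0)
  expect_true(is.na(d1$mean_displacement))
  expect_equal(d1$mean_depth, 4)

  # steps over long gaps are excluded from displacement
  gap <- make_fixes("A", t0 + c(0, 4800, 4800 * 10),
                    x = c(10, 16, 60), y = rep(50, 3), tag_depth = 4)
  dg <- daily_summaries(gap, fish, lk$bathy)
  expect_equal(sum(dg$n_steps), 1)
})

test_that("morph means weight fish then months equally", {
  daily <- data.frame(
    fish_id = c("a", "a", "b", "a"),
    date = as.Date(c("2009-09-01", "2009-09-02", "2009-09-01", "2009-10-01")),
    mean_displacement = c(0.02, 0.04, 0.10, 0.20),
    mean_depth = c(5, 7, 10, 8),
    mean_dist_from_bed = c(1, 3, 5, 2),
    n_steps = 5, n_fixes = 6)
  out <- morph_monthly_means(daily, c(a = "M", b = "M"))
  # Sep: fish a mean 0.03, fish b 0.10 -> month mean 0.065; Oct: 0.20
  expect_equal(out$monthly$mean_displacement, c(0.065, 0.20))
  # annual: mean of monthly means, months weighted equally
  expect_equal(out$annual$mean_displacement, mean(c(0.065, 0.20)))
})

test_that("observed displacement underestimates true swimming speed", {
  lk <- fixture_lake()
  pc <- pipeline_config()
  under <- logical(0)
  for (s in 1:10) {
    ph <- phenotype_spec(sprintf("F%02d", s), littoral_affinity = 0.4,
                         step_speed_mean = 0.06, depth_target = 6)
    tr <- simulate_track(lk, ph, t0, days = 6, seed = 100 + s)
    fx <- observe_track(tr, telemetry_spec(detection_prob = 1), seed = s)
    true_speed <- sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2)) /
      (60 * (length(tr$t) - 1)) / (tr$fork_length / 1000)
    gaps <- diff(as.numeric(fx$t))
    net <- sqrt(diff(fx$x)^2 + diff(fx$y)^2)
    obs <- mean(net / gaps) / (tr$fork_length / 1000)
    under <- c(under, obs <= true_speed)
  }
  expect_true(all(under))
})

test_that("the permutation morph test behaves under null and alternative", {
  set.seed(5)
  # identical fish values: the observed statistic is 0, so p = 1
  v0 <- rep(1.5, 10)
  p0 <- permutation_morph_test(v0, rep(c("X", "Y"), 5), 999, seed = 1)$p_value
  expect_gte(p0, 0.5)

  # strong contrast (effect 3 x SD), 10 + 10 fish
  v1 <- c(rnorm(10, 0, 1), rnorm(10, 3, 1))
  lab <- rep(c("X", "Y"), each = 10)
  r1 <- permutation_morph_test(v1, lab, 999, seed = 2)
  expect_lte(r1$p_value, 0.01)
  expect_gte(r1$p_value, 1 / 1000)

  expect_error(permutation_morph_test(1:4, c("X", "X", "Y", "Z"), 99, 1),
               "two morph")
  expect_warning(permutation_morph_test(c(1, 2, 3, 4),
                                        c("X", "X", "Y", "Y"), 50, 1),
                 "coarse")
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(77)
  ps <- replicate(200, {
    v <- rnorm(12)
    permutation_morph_test(v, rep(c("X", "Y"), each = 6), 199,
                           seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_true(all(ps >= 1 / 200 & ps <= 1))
})
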