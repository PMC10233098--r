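test_that("speed series follows the forward-difference definition", {
  tr <- line_trajectory(n = 5, dx = 1) # 1 unit per 0.025 s step
  expect_equal(speed_series(tr), rep(40, 4))
  still <- make_trajectory(rep(1, 4), rep(2, 4))
  expect_equal(speed_series(still), rep(0, 3))
  expect_length(speed_series(line_trajectory(n = 5)), 4)
  expect_error(speed_series(make_trajectory(1, 1)),
               class = "kinvae_degenerate_trajectory")
})

test_that("acceleration is the signed derivative of scalar speed", {
  expect_equal(acceleration_series(c(0, 40), dt = 0.025), 1600)
  expect_equal(acceleration_series(rep(7, 5), dt = 0.025), rep(0, 4))
  ramp <- c(0, 10, 25, 45)
  expect_equal(acceleration_series(rev(ramp), 0.025),
               -rev(acceleration_series(ramp, 0.025)))
  expect_error(acceleration_series(5, 0.025),
               class = "kinvae_degenerate_trajectory")
})

test_that("directional change measures turning angle per unit time", {
  straight <- line_trajectory(n = 6, dx = 2, dy = 1)
  expect_equal(directional_change_series(straight), rep(0, 4),
               tolerance = 1e-12)
  turn <- make_trajectory(c(0, 1, 1), c(0, 0, 1)) # right angle, unit steps
  expect_equal(directional_change_series(turn), (pi / 2) / 0.025)
  # zero-length displacements are skipped, shortening the series
  pause <- make_trajectory(c(0, 1, 1, 2), c(0, 0, 0, 1))
  expect_length(directional_change_series(pause), 2 - 1)
  expect_error(
    directional_change_series(make_trajectory(rep(0, 4), rep(0, 4))),
    class = "kinvae_degenerate_trajectory")
})

test_that("straightness is chord over path length", {
  expect_equal(straightness(line_trajectory(10, dx = 3, dy = 1)), 1)
  loop <- make_trajectory(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(straightness(loop), 0)
  bend <- make_trajectory(c(0, 1, 1), c(0, 0, 1))
  expect_equal(straightness(bend), sqrt(2) / 2)
  expect_error(straightness(make_trajectory(c(1, 1), c(2, 2))),
               class = "kinvae_degenerate_trajectory")
})

test_that("constant-velocity drags give degenerate feature values", {
  f <- trajectory_features(line_trajectory(n = 20, dx = 1.5))
  expect_equal(unname(f["sdSpeed"]), 0)
  expect_equal(unname(f["MeanSpeed"]), unname(f["MaxSpeed"]))
  expect_equal(unname(f["MeanSpeed"]), unname(f["MinSpeed"]))
  expect_equal(unname(f[c("MeanAcceleration", "MaxAcceleration",
                          "MinAcceleration", "sdAcceleration")]),
               rep(0, 4), ignore_attr = TRUE)
  expect_equal(unname(f["STH"]), 1)
  expect_equal(unname(f["DC"]), 0)
})

test_that("a unique interior speed peak is the max-peak statistic", {
  # symmetric triangular profile along a line: one interior speed maximum
  x <- cumsum(c(0, 1, 2, 3, 2, 1))
  tr <- make_trajectory(x, rep(0, length(x)))
  v <- speed_series(tr)
  f <- trajectory_features(tr)
  expect_equal(unname(f["MaxSpeed"]), max(v))
  g <- trajectory_features(tr, peaks = "global")
  expect_equal(unname(g["MaxSpeed"]), max(v))
  expect_equal(unname(g["MinSpeed"]), min(v))
})

test_that("every feature matches the brute-force oracle on random paths", {
  for (seed in 1:25) {
    tr <- random_trajectory(seed, n = 10)
    fast <- trajectory_features(tr)[feature_names()]
    slow <- brute_force_features(tr)
    expect_equal(fast, slow, tolerance = 1e-10)
    expect_lte(fast[["MinSpeed"]], fast[["MeanSpeed"]] + 1e-12)
    expect_lte(fast[["MeanSpeed"]], fast[["MaxSpeed"]] + 1e-12)
  }
})

test_that("features are scale-equivariant and time-reversal invariant", {
  for (seed in 1:10) {
    tr <- random_trajectory(seed)
    f <- trajectory_features(tr)
    c0 <- 3.7
    scaled <- make_trajectory(tr$x * c0, tr$y * c0)
    fs <- trajectory_features(scaled)
    lin <- c("MeanSpeed", "MaxSpeed", "MinSpeed", "sdSpeed",
             "MeanAcceleration", "MaxAcceleration", "MinAcceleration",
             "sdAcceleration", "MeanLength")
    expect_equal(fs[lin], f[lin] * c0, tolerance = 1e-10)
    expect_equal(fs[c("STH", "DC", "sdDC")], f[c("STH", "DC", "sdDC")],
                 tolerance = 1e-10)

    rev_tr <- make_trajectory(rev(tr$x), rev(tr$y))
    fr <- trajectory_features(rev_tr)
    keep <- c("STH", "MeanLength", "MeanSpeed", "sdSpeed")
    expect_equal(fr[keep], f[keep], tolerance = 1e-10)
  }
})

test_that("dataset assembly filters incorrect tasks and averages per task", {
  cfg <- cohort_config(n_per_group = 2, n_tasks = 5, n_traj_per_task = 3,
                       seed = 2)
  co <- generate_cohort(cfg)
  ds <- build_dataset(co)
  expect_s3_class(ds, "kinvae_features")
  expect_equal(nrow(ds), 4 * 5)
  expect_true(all(feature_names() %in% names(ds)))

  co$task_correct$correct[c(1, 7)] <- FALSE
  ds2 <- build_dataset(co)
  expect_equal(nrow(ds2), 4 * 5 - 2)

  # single participant, single task: the row is the mean over trajectories
  one <- co
  keep <- vapply(one$trajectories,
                 function(tr) tr$participant_id == "TD01" && tr$task_id == 1,
                 logical(1))
  one$trajectories <- one$trajectories[keep]
  one$labels <- one$labels["TD01"]
  one$task_correct <- data.frame(participant_id = "TD01", task_id = 1,
                                 correct = TRUE)
  row <- build_dataset(one)
  per_traj <- sapply(one$trajectories,
                     function(tr) trajectory_features(tr)[feature_names()])
  expect_equal(unlist(row[1, feature_names()]), rowMeans(per_traj),
               tolerance = 1e-12)
})

test_that("participants whose tasks are all incorrect are dropped loudly", {
  cfg <- cohort_config(n_per_group = 2, n_tasks = 5, n_traj_per_task = 2,
                       seed = 2)
  co <- generate_cohort(cfg)
  co$task_correct$correct[co$task_correct$participant_id == "TD01"] <- FALSE
  expect_warning(ds <- build_dataset(co), "TD01")
  expect_false("TD01" %in% ds$participant_id)
})

test_that("standardization computes, applies and refuses stats correctly", {
  ft <- small_table(seed = 4)
  std <- standardize(ft)
  z <- kinvae:::feature_matrix(std)
  expect_equal(unname(colMeans(z)), rep(0, 12), tolerance = 1e-9)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 12), tolerance = 1e-9)

  stats <- attr(std, "standardization_stats")
  other <- small_table(seed = 5)
  applied <- standardize(other, stats = stats)
  expect_gt(max(abs(colMeans(kinvae:::feature_matrix(applied)))), 1e-3)

  # idempotence holds exactly for (0, 1) stats
  unit <- data.frame(feature = feature_names(), mean = 0, sd = 1)
  expect_equal(kinvae:::feature_matrix(standardize(std, stats = unit)),
               kinvae:::feature_matrix(std))

  ft0 <- as.data.frame(ft)
  ft0$STH <- 0.5
  expect_error(standardize(kinvae:::new_feature_dataset(ft0)),
               regexp = "STH", class = "kinvae_zero_variance")
})
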