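test_that("generation is deterministic under a fixed seed", {
  r <- motion_recipe(duration = 2, seed = 90)
  s1 <- generate_wipe_sequence(r)
  s2 <- generate_wipe_sequence(r)
  expect_identical(s1$frames, s2$frames)
  s3 <- generate_wipe_sequence(motion_recipe(duration = 2, seed = 91))
  expect_false(identical(s1$frames, s3$frames))
})

test_that("a zero-jitter pure mediolateral wipe is a line segment in the frontal plane", {
  r <- motion_recipe(duration = 20, amp_is = 0, freq_ml = 0.5,
                     depth_sigma = 0, jitter_sigma = 0, seed = 92)
  s <- generate_wipe_sequence(r)
  rel <- joint_xyz(s, "wrist_r") - joint_xyz(s, "spine")
  expect_lt(diff(range(rel[, 1])), 1e-12)  # constant depth
  expect_lt(diff(range(rel[, 2])), 1e-12)  # constant height
  expect_equal(diff(range(rel[, 3])), 2 * r$amp_ml, tolerance = 1e-6)
  ax <- principal_axes(make_traj(rel))
  expect_lt(ax$axis_sizes[2], 1e-9)
  expect_lt(ax$axis_sizes[3], 1e-9)
})

test_that("halving the speed scale halves the mean wrist speed", {
  r1 <- motion_recipe(duration = 30, depth_sigma = 0, jitter_sigma = 0,
                      speed_scale = 1, seed = 93)
  r2 <- motion_recipe(duration = 60, depth_sigma = 0, jitter_sigma = 0,
                      speed_scale = 0.5, seed = 93)
  v <- vapply(list(r1, r2), function(r) {
    s <- generate_wipe_sequence(r)
    rel <- joint_xyz(s, "wrist_r") - joint_xyz(s, "spine")
    hodograph_kinematics(make_traj(rel, s$frequency))$v_mean
  }, numeric(1))
  expect_equal(v[2] / v[1], 0.5, tolerance = 0.02)
})

test_that("noise-free wrist path length matches the programmed Lissajous curve", {
  r <- motion_recipe(duration = 20, depth_sigma = 0, jitter_sigma = 0,
                     seed = 94)
  s <- generate_wipe_sequence(r)
  rel <- joint_xyz(s, "wrist_r") - joint_xyz(s, "spine")
  got <- hodograph_kinematics(make_traj(rel, s$frequency))$total_length
  # dense independent quadrature of the programmed path speed
  tt <- seq(0, 20 - 1 / 30, length.out = 200000)
  dml <- 2 * pi * r$freq_ml * r$amp_ml * cos(2 * pi * r$freq_ml * tt)
  dis <- 2 * pi * r$freq_is * r$amp_is * cos(2 * pi * r$freq_is * tt + r$phase)
  expected <- mean(sqrt(dml^2 + dis^2)) * (20 - 1 / 30)
  expect_equal(got, expected, tolerance = 0.01)
})

test_that("arm geometry is consistent: IK keeps segment lengths exact", {
  r <- motion_recipe(duration = 5, depth_sigma = 0, jitter_sigma = 0,
                     seed = 95)
  s <- generate_wipe_sequence(r)
  up <- rows_norm(joint_xyz(s, "elbow_r") - joint_xyz(s, "shoulder_r"))
  fo <- rows_norm(joint_xyz(s, "wrist_r") - joint_xyz(s, "elbow_r"))
  expect_lt(max(abs(up - r$upper_arm)), 1e-9)
  expect_lt(max(abs(fo - r$forearm)), 1e-9)
})

test_that("unreachable wrist targets are a recipe error", {
  r <- motion_recipe(duration = 1, amp_ml = 0.6, jitter_sigma = 0, seed = 96)
  expect_error(generate_wipe_sequence(r), "unreachable")
})

test_that("generated sequences pass validation and the full extraction", {
  s <- generate_wipe_sequence(motion_recipe(duration = 2, seed = 97))
  expect_silent(validate_sequence(s))
  trajs <- extract_relative_trajectories(build_lcs(s))
  expect_length(trajs, 17L)
})

test_that("cohort generation enforces group sizes and seeds", {
  expect_error(generate_cohort(n_per_group = 1L), "n_per_group")
  co <- generate_cohort(default_group_recipes(duration = 2),
                        n_per_group = 2L, seed = 5)
  expect_length(co$sequences, 6L)
  expect_equal(as.integer(table(co$groups)), rep(2L, 3))
  co2 <- generate_cohort(default_group_recipes(duration = 2),
                         n_per_group = 2L, seed = 5)
  expect_identical(co$sequences[[1]]$frames, co2$sequences[[1]]$frames)
})

test_that("synthetic cohort separates groups on wrist speed with high power", {
  flags_ae <- flags_as <- logical(20)
  for (rep in 1:20) {
    co <- generate_cohort(default_group_recipes(duration = 10),
                          n_per_group = c(16L, 17L, 10L), seed = 9000 + rep)
    v <- vapply(co$sequences, function(s) {
      rel <- joint_xyz(s, "wrist_r") - joint_xyz(s, "spine")
      hodograph_kinematics(make_traj(rel, s$frequency))$v_mean
    }, numeric(1))
    cmp <- group_comparison(v, co$groups)
    pw <- cmp$pairwise
    flags_ae[rep] <- pw$significant[pw$group1 == "adults" &
                                      pw$group2 == "elderly"]
    flags_as[rep] <- pw$significant[pw$group1 == "adults" &
                                      pw$group2 == "stroke"]
  }
  expect_gte(mean(flags_ae), 0.9)
  expect_gte(mean(flags_as), 0.9)
})

test_that("null cohorts (no group effect) keep the flag rate near alpha", {
  same <- list(adults = motion_recipe(duration = 8),
               elderly = motion_recipe(duration = 8),
               stroke = motion_recipe(duration = 8))
  flags <- logical(50)
  for (rep in 1:50) {
    co <- generate_cohort(same, n_per_group = 6L, seed = 9500 + rep)
    v <- vapply(co$sequences, function(s) {
      rel <- joint_xyz(s, "wrist_r") - joint_xyz(s, "spine")
      hodograph_kinematics(make_traj(rel, s$frequency))$v_mean
    }, numeric(1))
    pw <- group_comparison(v, co$groups)$pairwise
    flags[rep] <- pw$significant[pw$group1 == "adults" &
                                   pw$group2 == "elderly"]
  }
  expect_lte(mean(flags), 0.10)
})
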