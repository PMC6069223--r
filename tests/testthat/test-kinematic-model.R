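static_pose_seq <- function(pose, n = 10, f = 30) {
  skeleton_sequence(array(rep(pose, each = n), c(n, nrow(pose), 3L)),
                    rownames(pose), f)
}

test_that("calibration takes the median child-parent distance", {
  pose <- rbind(shoulder_l = c(0, 1.4, -0.2), elbow_l = c(0, 1.1, -0.2))
  links <- data.frame(child = "elbow_l", parent = "shoulder_l")
  lens <- calibrate_reference_lengths(static_pose_seq(pose), links)
  expect_equal(lens$length, 0.30, tolerance = 1e-12)

  seqs <- lapply(c(0.29, 0.30, 0.31), function(L) {
    p <- rbind(shoulder_l = c(0, 1.4, -0.2), elbow_l = c(0, 1.4 - L, -0.2))
    static_pose_seq(p)
  })
  lens3 <- calibrate_reference_lengths(seqs, links)
  expect_equal(lens3$length, 0.30, tolerance = 1e-12)

  expect_error(
    calibrate_reference_lengths(static_pose_seq(pose),
                                data.frame(child = "wrist_l",
                                           parent = "elbow_l")),
    "calibration error.*wrist_l")
})

test_that("noisy calibration recovers the true length within 5 mm", {
  poses <- generate_calibration_poses(seed = 5, jitter_sigma = 0.005)
  expect_equal(n_frames(poses$t_pose), 90L)
  lens <- calibrate_reference_lengths(poses)
  truth <- poses$t_pose$meta$true_lengths
  m <- merge(lens, truth, by = c("child", "parent"))
  expect_lt(max(abs(m$length.x - m$length.y)), 0.005)
})

test_that("zero-jitter calibration recovers true lengths exactly", {
  poses <- generate_calibration_poses(seed = 5, jitter_sigma = 0)
  lens <- calibrate_reference_lengths(poses)
  truth <- poses$t_pose$meta$true_lengths
  m <- merge(lens, truth, by = c("child", "parent"))
  expect_lt(max(abs(m$length.x - m$length.y)), 1e-12)
})

test_that("link correction pins every link length and preserves direction", {
  s <- generate_wipe_sequence(motion_recipe(duration = 2, seed = 9))
  lens <- calibrate_reference_lengths(
    generate_calibration_poses(seed = 1, jitter_sigma = 0))
  sc <- correct_link_lengths(s, lens)
  chain <- default_link_chain()
  for (k in seq_len(nrow(chain))) {
    d <- rows_norm(joint_xyz(sc, chain$child[k]) -
                     joint_xyz(sc, chain$parent[k]))
    expect_lt(max(abs(d - lens$length[k])), 1e-12)
    raw_dir <- joint_xyz(s, chain$child[k]) - joint_xyz(s, chain$parent[k])
    cor_dir <- joint_xyz(sc, chain$child[k]) - joint_xyz(sc, chain$parent[k])
    cosang <- rowSums(raw_dir * cor_dir) /
      (rows_norm(raw_dir) * rows_norm(cor_dir))
    expect_gt(min(cosang), 1 - 1e-12)
  }
  # already-correct input is a fixed point; correction is idempotent
  sc2 <- correct_link_lengths(sc, lens)
  expect_equal(sc2$frames, sc$frames, tolerance = 1e-12)
})

test_that("two-link chain correction matches hand forward kinematics", {
  pose <- rbind(root = c(0, 0, 0),
                mid = c(0.5, 0, 0),    # raw direction (1,0,0)
                tip = c(0.5, 0.9, 0))  # raw direction (0,1,0)
  s <- static_pose_seq(pose, n = 3)
  lens <- data.frame(child = c("mid", "tip"), parent = c("root", "mid"),
                     length = c(0.3, 0.25))
  chain <- data.frame(child = c("mid", "tip"), parent = c("root", "mid"))
  sc <- correct_link_lengths(s, lens, chain)
  expect_equal(unname(sc$frames[1, "mid", ]), c(0.3, 0, 0), tolerance = 1e-12)
  expect_equal(unname(sc$frames[1, "tip", ]), c(0.3, 0.25, 0),
               tolerance = 1e-12)
})

test_that("the kinematic model constructs 19 LCS and the thorax is identity in a global-aligned pose", {
  poses <- generate_calibration_poses(seed = 1, jitter_sigma = 0)
  lcs <- build_lcs(poses$t_pose)
  expect_equal(length(lcs$ids), 19L)
  thorax <- lcs$rotations[, , match(2L, lcs$ids), 1]
  expect_equal(thorax, diag(3), tolerance = 1e-12)
  # all orientation matrices orthonormal with det +1
  for (k in seq_along(lcs$ids)) {
    R <- lcs$rotations[, , k, 1]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("LCS construction is equivariant under rigid rotation", {
  s <- generate_wipe_sequence(motion_recipe(duration = 1, seed = 4))
  R <- random_rotation(7)
  s2 <- transform_sequence(s, R, c(0.3, -0.2, 1.1))
  lcs1 <- build_lcs(s)
  lcs2 <- build_lcs(s2)
  for (k in c(2, 14, 18)) {
    ki <- match(k, lcs1$ids)
    expect_lt(max(abs(lcs2$rotations[, , ki, 5] -
                        R %*% lcs1$rotations[, , ki, 5])), 1e-9)
  }
})

test_that("degenerate defining joints raise an error naming the LCS", {
  poses <- generate_calibration_poses(seed = 1, jitter_sigma = 0)
  s <- poses$t_pose
  s$frames[, "elbow_l", ] <- s$frames[, "shoulder_l", ]  # zero-length Y
  expect_error(build_lcs(s), "LCS 4")
})

test_that("default topology yields exactly 17 relative trajectories", {
  topo <- default_topology()
  expect_equal(nrow(topo), 17L)
  expect_setequal(topo$motion, c(1, 4, 5, 14:27))
  s <- generate_wipe_sequence(motion_recipe(duration = 1, seed = 2))
  trajs <- extract_relative_trajectories(build_lcs(s), topo)
  expect_length(trajs, 17L)
})

test_that("relative trajectory arithmetic is plain frame subtraction for identity parents", {
  # two-LCS set built by hand: parent at (1,0,0) with identity orientation
  conv <- data.frame(lcs_id = c(1L, 2L), name = c("child", "parent"),
                     origin_a = c("c0", "p0"), origin_b = "",
                     y_from = c("c0", "p0"), y_to = c("cy", "py"),
                     w_from = c("c0", "p0"), w_to = c("cz", "pz"))
  pose <- rbind(c0 = c(2, 0, 0), cy = c(2, 1, 0), cz = c(2, 0, 1),
                p0 = c(1, 0, 0), py = c(1, 1, 0), pz = c(1, 0, 1))
  s <- static_pose_seq(pose, n = 4)
  lcs <- build_lcs(s, conv)
  topo <- data.frame(motion = 1L, child = 1L, parent = 2L)
  tr <- extract_relative_trajectories(lcs, topo)[[1]]
  expect_equal(tr$points[1, ], c(1, 0, 0), tolerance = 1e-12)
})

test_that("relative trajectories are invariant under rigid transforms", {
  s <- generate_wipe_sequence(motion_recipe(duration = 1, seed = 6))
  trajs1 <- extract_relative_trajectories(build_lcs(s))
  for (rep in 1:3) {
    R <- random_rotation(100 + rep)
    set.seed(200 + rep)
    tvec <- stats::rnorm(3)
    trajs2 <- extract_relative_trajectories(build_lcs(
      transform_sequence(s, R, tvec)))
    for (lab in setdiff(names(trajs1), "pelvis_in_global"))
      expect_lt(max(abs(trajs2[[lab]]$points - trajs1[[lab]]$points)), 1e-9)
  }
})

test_that("mirror_label swaps sides both ways", {
  expect_equal(mirror_label("wrist_l_in_girdle_l"), "wrist_r_in_girdle_r")
  expect_equal(mirror_label(mirror_label("elbow_r_in_shoulder_r")),
               "elbow_r_in_shoulder_r")
})
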