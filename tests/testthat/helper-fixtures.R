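# In-code fixtures shared across tests.

rows_norm <- function(m) sqrt(rowSums(m * m))

make_traj <- function(points, frequency = 30, label = "test") {
  relative_trajectory(as.matrix(points), frequency, label = label)
}

# smooth seeded random trajectory kept away from the origin
random_traj <- function(n, seed, frequency = 30) {
  set.seed(seed)
  base <- c(stats::runif(1, 0.5, 1.5), stats::runif(1, 0.5, 1.5),
            stats::runif(1, 0.5, 1.5))
  p <- matrix(stats::rnorm(3 * n, sd = 0.2), n, 3)
  p <- sweep(p, 2, base, "+")
  make_traj(p, frequency)
}

circle_traj <- function(n, radius = 1, centre = c(0, 0, 0), frequency = 30) {
  th <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  make_traj(cbind(centre[1] + radius * cos(th),
                  centre[2] + radius * sin(th),
                  centre[3]), frequency)
}

# symmetric box grid with half-sizes a > b > c: its covariance is exactly
# diagonal, so the principal directions coincide with the box axes and the
# first extent is exactly 2a; displaced so the centre radius vector is
# well-posed
box_cloud_traj <- function(a = 0.4, b = 0.2, c = 0.1,
                           centre = c(0.8, 0.5, 0.3)) {
  g <- as.matrix(expand.grid(seq(-a, a, length.out = 5),
                             seq(-b, b, length.out = 4),
                             seq(-c, c, length.out = 3)))
  make_traj(sweep(g, 2, centre, "+"))
}

sphere_samples <- function(n, radius, centre, seed) {
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2)) * radius
  sweep(u, 2, centre, "+")
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# apply a rigid transform to every joint of every frame
transform_sequence <- function(seq, R, tvec = c(0, 0, 0)) {
  fr <- seq$frames
  for (j in seq_along(seq$joints))
    fr[, j, ] <- joint_xyz(seq, seq$joints[j]) %*% t(R) +
      matrix(tvec, nrow(fr), 3, byrow = TRUE)
  skeleton_sequence(fr, seq$joints, seq$frequency, subject_id = seq$subject_id,
                    meta = seq$meta)
}
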