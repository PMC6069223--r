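# Independent, loop-based reimplementation of the trajectory-shape
# quantities, used only as a cross-check oracle in tests. Deliberately naive:
# explicit element loops, no shared code with the package internals.

oracle_features <- function(p, f) {
  n <- nrow(p)
  enorm <- function(v) sqrt(v[1]^2 + v[2]^2 + v[3]^2)
  ecross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  v <- numeric(n)
  step <- numeric(n - 1)
  for (i in 1:(n - 1)) {
    step[i] <- enorm(p[i + 1, ] - p[i, ])
    v[i] <- f * step[i]
  }
  v[n] <- v[n - 1]
  travel <- numeric(n)
  for (i in 2:n) travel[i] <- travel[i - 1] + step[i - 1]

  S <- numeric(n - 1)
  alpha <- numeric(n - 1)
  for (i in 1:(n - 1)) {
    S[i] <- enorm(ecross(p[i, ], p[i + 1, ])) / 2
    h <- 2 * S[i] / enorm(p[i, ])
    a <- h / enorm(p[i + 1, ])
    alpha[i] <- asin(min(max(a, -1), 1))
  }
  omega <- alpha * 180 / pi * f
  radii <- numeric(n)
  for (i in 1:n) radii[i] <- enorm(p[i, ])

  centre <- c(mean(p[, 1]), mean(p[, 2]), mean(p[, 3]))
  q <- matrix(0, n, 3)
  for (i in 1:n) q[i, ] <- p[i, ] - centre
  inert <- matrix(0, 3, 3)
  for (i in 1:n)
    inert <- inert + (sum(q[i, ]^2) * diag(3) - q[i, ] %*% t(q[i, ]))
  ev <- eigen(inert, symmetric = TRUE)
  g1 <- ev$vectors[, 3]
  if (g1[which.max(abs(g1))] < 0) g1 <- -g1
  cx <- ecross(centre, g1)
  g2 <- cx / enorm(cx)
  g3 <- ecross(g1, g2)
  G <- cbind(g1, g2, g3)
  qmin <- rep(Inf, 3); qmax <- rep(-Inf, 3)
  for (i in 1:n)
    for (j in 1:3) {
      pr <- sum(q[i, ] * G[, j])
      if (pr < qmin[j]) qmin[j] <- pr
      if (pr > qmax[j]) qmax[j] <- pr
    }
  B1 <- matrix(0, 3, 3); B2 <- matrix(0, 3, 3)
  phi <- numeric(3); lb <- numeric(3)
  for (j in 1:3) {
    B1[j, ] <- centre + qmin[j] * G[, j]
    B2[j, ] <- centre + qmax[j] * G[, j]
    ca <- sum(B1[j, ] * B2[j, ]) / (enorm(B1[j, ]) * enorm(B2[j, ]))
    phi[j] <- acos(min(max(ca, -1), 1)) * 180 / pi
    lb[j] <- enorm(B1[j, ] - B2[j, ])
  }
  nm1 <- n - 1
  list(total_length = travel[n],
       v_mean = sum(v) / n,
       v_std = sqrt(sum((v - sum(v) / n)^2) / (n - 1)),
       v_max = max(v),
       swept_area = sum(S),
       total_angle = sum(alpha) * 180 / pi,
       omega_mean = sum(omega) / nm1,
       omega_std = sqrt(sum((omega - sum(omega) / nm1)^2) / (nm1 - 1)),
       omega_max = max(omega),
       omega_from_radius = (180 / pi) * (sum(v) / n) / mean(radii),
       centre = centre, G = G, q_min = qmin, q_max = qmax,
       B1 = B1, B2 = B2, view_angles = phi, axis_sizes = lb,
       rhomboid_area = lb[1] * lb[2] / 2,
       diamond_volume = lb[1] * lb[2] / 2 * lb[3] / 3)
}

# circumsphere of 4 non-coplanar points (closed form via the linear system
# |x - c|^2 = r^2 differences)
oracle_circumsphere <- function(p) {
  A <- 2 * (p[2:4, ] - matrix(p[1, ], 3, 3, byrow = TRUE))
  b <- rowSums(p[2:4, ]^2) - sum(p[1, ]^2)
  centre <- solve(A, b)
  list(centre = centre, radius = sqrt(sum((p[1, ] - centre)^2)))
}

expect_rel_equal <- function(actual, expected, tol = 1e-12) {
  scale <- pmax(abs(expected), 1)
  testthat::expect_lt(max(abs(actual - expected) / scale), tol)
}
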