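#' Principal axes of a trajectory point cloud
#'
#' The trajectory points are treated as a unit-mass point cloud. After
#' centring on the cloud mean, the total inertia matrix
#' `I = sum((q_i' q_i) E - q_i q_i')` is decomposed; the first principal axis
#' G1 is the direction of maximum cloud spread (the minimum-inertia
#' eigenvector). The second axis is perpendicular to the plane spanned by G1
#' and the radius vector of the cloud centre, `G2 = unit(p_mean x G1)`, and
#' the third completes the right-handed triad, `G3 = G1 x G2`. Axis extents
#' are the min/max projections of the centred points on each axis; the end
#' points `B1_i = p_mean + Qmin_i G_i` and `B2_i = p_mean + Qmax_i G_i` give
#' per-axis angles of view from the parent-LCS origin and axis sizes
#' `LB_i = ||B1_i - B2_i||`.
#'
#' When `p_mean` is (near-)parallel to G1 or (near-)zero, G2 is undefined by
#' the cross-product construction; a deterministic fallback perpendicular
#' (smallest-component rule) is used and the result flagged.
#'
#' @param traj a [relative_trajectory()] with N >= 3 non-coincident points.
#' @return A list of class `principal_axes`: `centre` (m), `G` (3x3 columns
#'   G1,G2,G3), `q_min`, `q_max` (per-axis extents, m), `B1`, `B2` (3x3, row i
#'   = end points of axis i, m), `view_angles` (deg, length 3), `axis_sizes`
#'   (m, length 3), `inertia` (3x3), `flag` (character).
#' @export
principal_axes <- function(traj) {
  stopifnot(inherits(traj, "relative_trajectory"))
  p <- traj$points
  n <- nrow(p)
  if (n < 3L) stop("insufficient data: need at least 3 points", call. = FALSE)
  centre <- colMeans(p)
  q <- sweep(p, 2L, centre)
  C <- crossprod(q)                     # sum q_i q_i'
  if (sum(diag(C)) < 1e-24)
    stop("degenerate cloud: all points coincident", call. = FALSE)
  inertia <- sum(diag(C)) * diag(3) - C # sum (q'q)E - q q'
  ev <- eigen(inertia, symmetric = TRUE)
  g1 <- ev$vectors[, 3L]                # minimum inertia = maximum spread
  # deterministic sign: largest-magnitude component positive
  imax <- which.max(abs(g1))
  if (g1[imax] < 0) g1 <- -g1
  flag <- ""
  cx <- cross3(centre, g1)
  if (vec_norm(cx) < 1e-9 * max(vec_norm(centre), 1)) {
    # fallback: unit vector perpendicular to g1 via smallest-component rule
    e <- diag(3)[, which.min(abs(g1))]
    cx <- cross3(g1, e)
    flag <- "g2_fallback"
  }
  g2 <- cx / vec_norm(cx)
  g3 <- cross3(g1, g2)
  G <- cbind(G1 = g1, G2 = g2, G3 = g3)
  QG <- q %*% G
  q_min <- unname(apply(QG, 2L, min))
  q_max <- unname(apply(QG, 2L, max))
  B1 <- t(vapply(1:3, function(i) centre + q_min[i] * G[, i], numeric(3)))
  B2 <- t(vapply(1:3, function(i) centre + q_max[i] * G[, i], numeric(3)))
  view_angles <- vapply(1:3, function(i) {
    d <- vec_norm(B1[i, ]) * vec_norm(B2[i, ])
    if (d < 1e-24) return(NA_real_)
    deg(acos(clamp(sum(B1[i, ] * B2[i, ]) / d, -1, 1)))
  }, numeric(1))
  structure(list(centre = centre, G = G, q_min = q_min, q_max = q_max,
                 B1 = B1, B2 = B2, view_angles = view_angles,
                 axis_sizes = q_max - q_min, inertia = inertia, flag = flag),
            class = "principal_axes")
}

#' Rhomboid area and diamond volume of the principal axes
#'
#' The end points of the first two principal axes span a rhomboid of area
#' `LB1 * LB2 / 2`; together with the third axis they define a bipyramid
#' ("diamond") of volume `S_mid * LB3 / 3`. Values are returned in SI (m^2,
#' m^3); conversion to the reporting units (cm^2, cm^3) happens only in the
#' feature vector.
#'
#' @param axes a [principal_axes()] result.
#' @return A list with `rhomboid_area` (m^2) and `diamond_volume` (m^3).
#' @export
rhomboid_diamond <- function(axes) {
  stopifnot(inherits(axes, "principal_axes"))
  s_mid <- axes$axis_sizes[1L] * axes$axis_sizes[2L] / 2
  list(rhomboid_area = s_mid, diamond_volume = s_mid * axes$axis_sizes[3L] / 3)
}

#' Least-squares sphere fit of a trajectory cloud
#'
#' Algebraic (Kasa) linear least squares gives a closed-form initial centre
#' and radius, refined by geometric least squares on the radial residuals
#' `||p_i - c|| - r` (Levenberg-Marquardt). A coplanar or collinear cloud
#' makes the algebraic system singular; the fit is then flagged degenerate and
#' the radius reported as `NA` rather than silently large.
#'
#' @param traj a [relative_trajectory()] with N >= 4 points.
#' @return A list of class `sphere_fit`: `centre` (m), `radius` (m),
#'   `centre_dist` (distance of the centre from the parent-LCS origin, m),
#'   `resid_mean` (mean absolute radial residual, m), `resid_std` (sd of
#'   signed residuals, m), `flag`.
#' @export
fit_sphere <- function(traj) {
  stopifnot(inherits(traj, "relative_trajectory"))
  p <- traj$points
  n <- nrow(p)
  if (n < 4L) stop("insufficient data: need at least 4 points", call. = FALSE)
  degen <- structure(list(centre = rep(NA_real_, 3), radius = NA_real_,
                          centre_dist = NA_real_, resid_mean = NA_real_,
                          resid_std = NA_real_, flag = "degenerate"),
                     class = "sphere_fit")
  # coplanarity check on the centred cloud
  q <- sweep(p, 2L, colMeans(p))
  sv <- svd(q, nu = 0, nv = 0)$d
  if (sv[1L] < 1e-12 || sv[4 - 1] / sv[1L] < 1e-8) return(degen)
  A <- cbind(2 * p, 1)
  b <- rowSums(p * p)
  fit <- qr(A)
  if (fit$rank < 4L) return(degen)
  beta <- qr.coef(fit, b)
  centre <- beta[1:3]
  r2 <- beta[4L] + sum(centre^2)
  if (!is.finite(r2) || r2 <= 0) return(degen)
  r <- sqrt(r2)
  # geometric refinement
  res_fn <- function(par) rows_norm(sweep(p, 2L, par[1:3])) - par[4L]
  ref <- try(minpack.lm::nls.lm(par = c(centre, r), fn = res_fn,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 100)),
             silent = TRUE)
  if (!inherits(ref, "try-error") && all(is.finite(ref$par)) &&
      ref$par[4L] > 0) {
    centre <- ref$par[1:3]
    r <- ref$par[4L]
  }
  resid <- rows_norm(sweep(p, 2L, centre)) - r
  structure(list(centre = centre, radius = r,
                 centre_dist = vec_norm(centre),
                 resid_mean = mean(abs(resid)),
                 resid_std = stats::sd(resid), flag = ""),
            class = "sphere_fit")
}
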