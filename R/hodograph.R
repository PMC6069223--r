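#' Hodograph velocity kinematics of a relative trajectory
#'
#' From the point sequence `p_i` sampled at frequency `f`, the instantaneous
#' speed is the forward difference `v_i = f * ||p_{i+1} - p_i||` (the final
#' value is repeated so the speed series has length N), the cumulative travel
#' is `L_i = sum ||p_{k+1} - p_k||`, and the summary statistics are the mean,
#' standard deviation (N-1 divisor) and maximum of the speed series.
#'
#' @param traj a [relative_trajectory()] with N >= 2 points.
#' @return A list of class `hodograph` with `speeds` (length N, m/s), `travel`
#'   (length N, cumulative metres, `travel[1] = 0`), `total_length` (m),
#'   `v_mean`, `v_std`, `v_max` (m/s).
#' @export
hodograph_kinematics <- function(traj) {
  stopifnot(inherits(traj, "relative_trajectory"))
  p <- traj$points
  n <- nrow(p)
  if (n < 2L) stop("insufficient data: need at least 2 points", call. = FALSE)
  step <- rows_norm(p[-1L, , drop = FALSE] - p[-n, , drop = FALSE])
  v <- traj$frequency * step
  speeds <- c(v, v[n - 1L])
  travel <- c(0, cumsum(step))
  structure(list(speeds = speeds, travel = travel,
                 total_length = travel[n],
                 v_mean = mean(speeds), v_std = stats::sd(speeds),
                 v_max = max(speeds)),
            class = "hodograph")
}

#' Swept area, total angle and angular-velocity statistics
#'
#' Each consecutive point pair spans, with the parent-LCS origin `o`, a
#' triangle of area `S_i = ||p_i x p_{i+1}|| / 2`; their sum is the total
#' swept area. The angle between successive rays is
#' `alpha_i = arcsin(h_i / ||p_{i+1}||)` with `h_i = 2 S_i / ||p_i||` (the
#' triangle height from the origin ray), the argument clamped to `[-1, 1]`
#' against floating-point overshoot; this construction caps each per-step
#' angle at 90 degrees, so steps subtending more are under-counted. The total
#' angular travel is the degree sum of the `alpha_i`; instantaneous angular
#' speeds are `omega_i = (180/pi) f alpha_i` (deg/s). A radius-based mean
#' angular velocity, `(180/pi) * v_mean / mean(||p_i||)`, is also returned.
#'
#' @param traj a [relative_trajectory()] with N >= 2 points, none exactly at
#'   the parent-LCS origin.
#' @param hodo optional precomputed [hodograph_kinematics()] result.
#' @return A list with `swept_area` (m^2), `total_angle` (deg), `angles`
#'   (rad, length N-1), `omega` (deg/s, length N-1), `omega_mean`,
#'   `omega_std`, `omega_max` (deg/s), `omega_from_radius` (deg/s).
#' @export
swept_area_and_angle <- function(traj, hodo = NULL) {
  stopifnot(inherits(traj, "relative_trajectory"))
  p <- traj$points
  n <- nrow(p)
  if (n < 2L) stop("insufficient data: need at least 2 points", call. = FALSE)
  r <- rows_norm(p)
  if (any(r < 1e-12))
    stop("degenerate ray: trajectory point coincides with the LCS origin ",
         "(frame ", which(r < 1e-12)[1L], ")", call. = FALSE)
  a <- p[-n, , drop = FALSE]
  b <- p[-1L, , drop = FALSE]
  S <- rows_norm(rows_cross(a, b)) / 2
  h <- 2 * S / r[-n]
  alpha <- asin(clamp(h / r[-1L], -1, 1))
  omega <- deg(alpha) * traj$frequency
  if (is.null(hodo)) hodo <- hodograph_kinematics(traj)
  list(swept_area = sum(S),
       total_angle = sum(deg(alpha)),
       angles = alpha,
       omega = omega,
       omega_mean = mean(omega),
       omega_std = stats::sd(omega),
       omega_max = max(omega),
       omega_from_radius = deg(hodo$v_mean / mean(r)))
}
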