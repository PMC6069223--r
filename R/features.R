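#' Definitions of the 41 trajectory-shape parameters
#'
#' Index, short name and reporting unit of every parameter in the standard
#' panel: hodograph travel/angle/velocity statistics (1-9), principal-axes
#' reach geometry (10-30), sphere-fit quantities (31-37) and convex-hull
#' workspace metrics (38-41). Values are computed in SI internally and
#' converted to these units only at reporting.
#'
#' @return A `data.frame` with columns `param_index`, `param_name`, `unit`.
#' @export
feature_definitions <- function() {
  data.frame(
    param_index = 1:41,
    param_name = c(
      "trajectory_length",                            # 1
      "total_angle",                                  # 2
      "velocity_mean", "velocity_std", "velocity_max",          # 3-5
      "angular_velocity_mean", "angular_velocity_std",
      "angular_velocity_max",                         # 6-8
      "angular_velocity_from_radius",                 # 9
      "rhomboid_area", "diamond_volume",              # 10-11
      "view_angle_axis1", "view_angle_axis2",         # 12-13
      "axis1_size", "axis2_size",                     # 14-15
      "axes_origin_x", "axes_origin_y", "axes_origin_z",        # 16-18
      "axis1_end1_x", "axis1_end1_y", "axis1_end1_z",           # 19-21
      "axis1_end2_x", "axis1_end2_y", "axis1_end2_z",           # 22-24
      "axis2_end1_x", "axis2_end1_y", "axis2_end1_z",           # 25-27
      "axis2_end2_x", "axis2_end2_y", "axis2_end2_z",           # 28-30
      "sphere_radius", "sphere_centre_dist",          # 31-32
      "sphere_resid_mean", "sphere_resid_std",        # 33-34
      "sphere_centre_x", "sphere_centre_y", "sphere_centre_z",  # 35-37
      "hull_surface_area", "hull_conic_volume",       # 38-39
      "sphere_solid_angle", "surface_solid_angle"),   # 40-41
    unit = c("m", "deg", rep("m/s", 3), rep("deg/s", 3), "deg/s",
             "cm2", "cm3", "deg", "deg", rep("mm", 2), rep("mm", 15),
             rep("mm", 7), "mm2", "mm3", "sr", "sr"),
    stringsAsFactors = FALSE)
}

#' Compute the 41-parameter feature vector of one relative trajectory
#'
#' Runs [hodograph_kinematics()], [swept_area_and_angle()],
#' [principal_axes()], [rhomboid_diamond()], [fit_sphere()] and
#' [hull_metrics()] on one trajectory and assembles the 41 named parameters in
#' standard order and reporting units (see [feature_definitions()]).
#' Degenerate sub-results (coplanar sphere fits, flat hulls, fallback second
#' axes) are carried as `NA` values with a flag channel rather than silently
#' poisoning the vector. The total swept sector area is returned as an
#' auxiliary attribute (`swept_area`, m^2); it is not one of the 41
#' parameters.
#'
#' @param traj a [relative_trajectory()] with N >= 4 points.
#' @return A list of class `feature_vector`: `values` (named numeric, length
#'   41, reporting units), `flags` (character, length 41), `label`, `n`,
#'   `frequency`, plus attribute `swept_area`.
#' @export
compute_feature_vector <- function(traj) {
  stopifnot(inherits(traj, "relative_trajectory"))
  n <- nrow(traj$points)
  if (n < 4L) stop("insufficient data: need at least 4 points", call. = FALSE)
  defs <- feature_definitions()
  values <- stats::setNames(rep(NA_real_, 41L), defs$param_name)
  flags <- stats::setNames(rep("", 41L), defs$param_name)

  hodo <- hodograph_kinematics(traj)
  swp <- swept_area_and_angle(traj, hodo)
  values[1L] <- hodo$total_length
  values[2L] <- swp$total_angle
  values[3:5] <- c(hodo$v_mean, hodo$v_std, hodo$v_max)
  values[6:8] <- c(swp$omega_mean, swp$omega_std, swp$omega_max)
  values[9L] <- swp$omega_from_radius

  axes <- principal_axes(traj)
  rd <- rhomboid_diamond(axes)
  values[10L] <- rd$rhomboid_area * 1e4        # m^2 -> cm^2
  values[11L] <- rd$diamond_volume * 1e6       # m^3 -> cm^3
  values[12:13] <- axes$view_angles[1:2]
  values[14:15] <- axes$axis_sizes[1:2] * 1e3  # m -> mm
  values[16:18] <- axes$centre * 1e3
  values[19:21] <- axes$B1[1L, ] * 1e3
  values[22:24] <- axes$B2[1L, ] * 1e3
  values[25:27] <- axes$B1[2L, ] * 1e3
  values[28:30] <- axes$B2[2L, ] * 1e3
  if (nzchar(axes$flag)) flags[c(12:15, 19:30)] <- axes$flag

  sph <- fit_sphere(traj)
  values[31L] <- sph$radius * 1e3
  values[32L] <- sph$centre_dist * 1e3
  values[33:34] <- c(sph$resid_mean, sph$resid_std) * 1e3
  values[35:37] <- sph$centre * 1e3
  if (nzchar(sph$flag)) flags[31:37] <- sph$flag

  hm <- hull_metrics(traj, sph)
  values[38L] <- hm$surface_area * 1e6         # m^2 -> mm^2
  values[39L] <- hm$conic_volume * 1e9         # m^3 -> mm^3
  values[40L] <- hm$sphere_solid_angle
  values[41L] <- hm$surface_solid_angle
  if (nzchar(hm$flag)) flags[38:41] <- hm$flag
  if (nzchar(sph$flag)) flags[40L] <- sph$flag

  out <- structure(list(values = values, flags = flags, label = traj$label,
                        n = n, frequency = traj$frequency),
                   class = "feature_vector")
  attr(out, "swept_area") <- swp$swept_area
  out
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("feature_vector '%s' (N=%d @ %g Hz)\n", x$label, x$n,
              x$frequency))
  print(utils::head(as.data.frame(x), 10L))
  cat("  ... (41 parameters)\n")
  invisible(x)
}

#' @export
as.data.frame.feature_vector <- function(x, ...) {
  d <- feature_definitions()
  data.frame(trajectory = x$label, param_index = d$param_index,
             param_name = d$param_name, unit = d$unit,
             value = unname(x$values), flag = unname(x$flags),
             stringsAsFactors = FALSE)
}

#' Compute feature vectors for a set of trajectories
#'
#' @param trajs list of [relative_trajectory()] objects (e.g. from
#'   [extract_relative_trajectories()]).
#' @return A long `data.frame` with columns
#'   `trajectory,param_index,param_name,unit,value,flag` (41 rows per
#'   trajectory).
#' @export
features_table <- function(trajs) {
  if (inherits(trajs, "relative_trajectory")) trajs <- list(trajs)
  do.call(rbind, lapply(trajs, function(tr)
    as.data.frame(compute_feature_vector(tr))))
}

#' Write a feature table to CSV or JSON
#'
#' @param features long `data.frame` from [features_table()].
#' @param path output path; a `.json` extension selects the JSON mirror.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(features, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  else
    utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
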