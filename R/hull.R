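#' 3D convex hull by incremental insertion
#'
#' Builds the convex hull of a 3D point cloud with the classic incremental
#' (beneath-beyond) algorithm: an initial extreme tetrahedron is grown by
#' deleting the faces visible from each new point and stitching new faces to
#' the horizon edges. Faces are returned consistently oriented with outward
#' normals. Collinear or coplanar clouds are detected and returned as
#' degenerate hulls carrying the planar 2D hull (area via the shoelace
#' formula) instead.
#'
#' @param pts numeric `n x 3` matrix.
#' @param tol relative tolerance for visibility/degeneracy tests, scaled by
#'   the cloud diameter.
#' @return A list: `degenerate` (logical), and either `faces` (`m x 3` vertex
#'   index matrix, outward oriented) for a full-dimensional hull, or `type`
#'   (`"point"`, `"collinear"`, `"coplanar"`), `planar_area` (m^2) and
#'   `planar_faces` (fan triangulation of the planar hull, possibly `NULL`)
#'   for degenerate clouds. Always carries `vertices = pts`.
#' @export
convex_hull_3d <- function(pts, tol = 1e-9) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3L)
  n <- nrow(pts)
  diam <- max(apply(pts, 2L, function(v) diff(range(v))), 0)
  eps <- max(tol * max(diam, 1), 1e-300)
  if (n < 2L || diam < eps)
    return(list(degenerate = TRUE, type = "point", planar_area = 0,
                planar_faces = NULL, vertices = pts))

  # initial extreme points
  i1 <- order(pts[, 1L], pts[, 2L], pts[, 3L])[1L]
  d1 <- rows_norm(sweep(pts, 2L, pts[i1, ]))
  i2 <- which.max(d1)
  u <- (pts[i2, ] - pts[i1, ]) / d1[i2]
  rel <- sweep(pts, 2L, pts[i1, ])
  perp <- rel - outer(drop(rel %*% u), u)
  dperp <- rows_norm(perp)
  i3 <- which.max(dperp)
  if (dperp[i3] < eps)
    return(list(degenerate = TRUE, type = "collinear", planar_area = 0,
                planar_faces = NULL, vertices = pts))
  nrm0 <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  nrm0 <- nrm0 / vec_norm(nrm0)
  dplane <- abs(drop(rel %*% nrm0))
  i4 <- which.max(dplane)
  if (dplane[i4] < eps)
    return(.planar_hull(pts, nrm0, i1))

  centroid <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(f) {
    a <- pts[f[1L], ]
    nn <- cross3(pts[f[2L], ] - a, pts[f[3L], ] - a)
    if (sum(nn * (centroid - a)) > 0) f[c(1L, 3L, 2L)] else f
  }
  faces <- t(apply(faces, 1L, orient))
  face_normal <- function(f) {
    a <- pts[f[1L], ]
    cross3(pts[f[2L], ] - a, pts[f[3L], ] - a)  # unnormalized outward
  }
  normals <- t(apply(faces, 1L, face_normal))
  offsets <- rowSums(normals * pts[faces[, 1L], , drop = FALSE])

  for (ip in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    p <- pts[ip, ]
    # visibility with a normal-scaled tolerance
    vis <- drop(normals %*% p) - offsets >
      eps * rows_norm(normals)
    if (!any(vis)) next
    vf <- faces[vis, , drop = FALSE]
    # horizon: undirected edges used exactly once among visible faces
    ed <- rbind(vf[, c(1L, 2L)], vf[, c(2L, 3L)], vf[, c(3L, 1L)])
    key <- paste(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
    horizon <- ed[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    if (nrow(horizon) == 0L) next  # numerically inconsistent; keep hull as-is
    newf <- cbind(horizon, ip)
    newf <- t(apply(newf, 1L, orient))
    faces <- rbind(faces[!vis, , drop = FALSE], newf)
    nn <- t(apply(newf, 1L, face_normal))
    normals <- rbind(normals[!vis, , drop = FALSE], nn)
    offsets <- c(offsets[!vis], rowSums(nn * pts[newf[, 1L], , drop = FALSE]))
  }
  list(degenerate = FALSE, faces = faces, vertices = pts)
}

.planar_hull <- function(pts, nrm, i1) {
  # orthonormal in-plane basis
  e1 <- cross3(nrm, diag(3)[, which.min(abs(nrm))])
  e1 <- e1 / vec_norm(e1)
  e2 <- cross3(nrm, e1)
  rel <- sweep(pts, 2L, pts[i1, ])
  uv <- cbind(drop(rel %*% e1), drop(rel %*% e2))
  h <- grDevices::chull(uv)
  if (length(h) < 3L)
    return(list(degenerate = TRUE, type = "collinear", planar_area = 0,
                planar_faces = NULL, vertices = pts))
  x <- uv[h, 1L]; y <- uv[h, 2L]
  area <- abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
  fan <- if (length(h) >= 3L)
    cbind(h[1L], h[seq(2L, length(h) - 1L)], h[seq(3L, length(h))])
  list(degenerate = TRUE, type = "coplanar", planar_area = area,
       planar_faces = fan, vertices = pts)
}

#' Solid angle of a triangle seen from the origin
#'
#' Van Oosterom-Strackee formula for the (unsigned) solid angle subtended at
#' the origin by the triangle with vertex position vectors `r1,r2,r3`.
#'
#' @param r1,r2,r3 numeric 3-vectors.
#' @return Solid angle in steradians, in `[0, 2*pi]`.
#' @export
triangle_solid_angle <- function(r1, r2, r3) {
  n1 <- vec_norm(r1); n2 <- vec_norm(r2); n3 <- vec_norm(r3)
  num <- sum(r1 * cross3(r2, r3))
  den <- n1 * n2 * n3 + sum(r1 * r2) * n3 + sum(r1 * r3) * n2 +
    sum(r2 * r3) * n1
  abs(2 * atan2(num, den))
}

#' Workspace hull metrics of a relative trajectory
#'
#' Reachable-workspace descriptors built from the convex hull of the
#' trajectory cloud and from its fitted sphere, all seen from the parent-LCS
#' origin:
#' \itemize{
#'   \item triangulated surface area: sum of the hull facet areas (m^2);
#'   \item conic volume with apex at the LCS origin: signed accumulation of
#'     the origin-apex tetrahedra over the outward-oriented facets, which
#'     equals the enclosed hull volume for any apex location (m^3);
#'   \item solid angle of the fitted sphere: `2*pi*(1 - sqrt(1 - (r/d)^2))`
#'     for centre distance `d > r`, else the full sphere `4*pi` (sr);
#'   \item solid angle of the triangulated surface: `4*pi` when the origin
#'     lies strictly inside the hull, otherwise the sum of the unsigned
#'     van Oosterom-Strackee angles of the origin-facing facets, capped at
#'     `4*pi` (sr).
#' }
#' A coplanar cloud yields a flagged degenerate result: the planar 2D hull
#' area, zero volume, and the solid angle of the planar triangulation.
#'
#' @param traj a [relative_trajectory()] with N >= 4 points.
#' @param sphere optional [fit_sphere()] result (computed if missing).
#' @return A list of class `hull_metrics`: `surface_area` (m^2),
#'   `conic_volume` (m^3), `sphere_solid_angle` (sr), `surface_solid_angle`
#'   (sr), `flag`.
#' @export
hull_metrics <- function(traj, sphere = NULL) {
  stopifnot(inherits(traj, "relative_trajectory"))
  p <- traj$points
  if (nrow(p) < 4L)
    stop("insufficient data: need at least 4 points", call. = FALSE)
  if (is.null(sphere)) sphere <- fit_sphere(traj)
  sph_sa <- if (identical(sphere$flag, "degenerate") ||
                !is.finite(sphere$radius)) {
    NA_real_
  } else if (sphere$centre_dist > sphere$radius) {
    2 * pi * (1 - sqrt(1 - (sphere$radius / sphere$centre_dist)^2))
  } else 4 * pi

  hull <- convex_hull_3d(p)
  if (hull$degenerate) {
    surf_sa <- 0
    if (!is.null(hull$planar_faces)) {
      surf_sa <- sum(apply(hull$planar_faces, 1L, function(f)
        triangle_solid_angle(p[f[1L], ], p[f[2L], ], p[f[3L], ])))
      surf_sa <- min(surf_sa, 4 * pi)
    }
    return(structure(list(surface_area = hull$planar_area, conic_volume = 0,
                          sphere_solid_angle = sph_sa,
                          surface_solid_angle = surf_sa,
                          flag = paste0("degenerate_", hull$type)),
                     class = "hull_metrics"))
  }
  fa <- hull$faces
  a <- p[fa[, 1L], , drop = FALSE]
  b <- p[fa[, 2L], , drop = FALSE]
  cc <- p[fa[, 3L], , drop = FALSE]
  cr <- rows_cross(b - a, cc - a)
  area <- sum(rows_norm(cr)) / 2
  vol <- abs(sum(rowSums(a * rows_cross(b, cc)))) / 6
  offs <- rowSums(cr * a) / rows_norm(cr)  # signed distance of facet plane
  scale <- max(rows_norm(p))
  if (all(offs > 1e-9 * scale)) {
    surf_sa <- 4 * pi  # origin strictly inside the hull
  } else {
    facing <- which(offs < 0)
    surf_sa <- 0
    for (k in facing)
      surf_sa <- surf_sa +
        triangle_solid_angle(a[k, ], b[k, ], cc[k, ])
    surf_sa <- min(surf_sa, 4 * pi)
  }
  structure(list(surface_area = area, conic_volume = vol,
                 sphere_solid_angle = sph_sa, surface_solid_angle = surf_sa,
                 flag = ""),
            class = "hull_metrics")
}
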