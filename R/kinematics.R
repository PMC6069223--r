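#' Calibrate per-subject segment lengths from static poses
#'
#' Depth-camera skeletons jitter in depth, so segment (link) lengths vary from
#' frame to frame. From one or more static calibration pose recordings (e.g.
#' T-pose, wide pose, upright pose held ~3 s each) the reference length of
#' each link is taken as the median over all calibration frames of the
#' Euclidean child-parent distance; the median is robust to occasional
#' tracking spikes.
#'
#' @param pose_sequences a [skeleton_sequence()] or list of them.
#' @param links `data.frame` with columns `child`, `parent` (joint labels);
#'   defaults to [default_link_chain()].
#' @return A `data.frame` `child,parent,length` (metres), class
#'   `segment_lengths`.
#' @export
calibrate_reference_lengths <- function(pose_sequences,
                                        links = default_link_chain()) {
  if (inherits(pose_sequences, "skeleton_sequence"))
    pose_sequences <- list(pose_sequences)
  stopifnot(length(pose_sequences) >= 1L)
  len <- numeric(nrow(links))
  for (k in seq_len(nrow(links))) {
    d <- unlist(lapply(pose_sequences, function(s) {
      if (!all(c(links$child[k], links$parent[k]) %in% s$joints))
        return(NULL)
      rows_norm(joint_xyz(s, links$child[k]) - joint_xyz(s, links$parent[k]))
    }))
    if (is.null(d) || length(d) == 0L)
      stop("calibration error: link ", links$child[k], "-", links$parent[k],
           " absent from all calibration sequences", call. = FALSE)
    len[k] <- stats::median(d)
  }
  out <- data.frame(child = links$child, parent = links$parent, length = len,
                    stringsAsFactors = FALSE)
  if (any(out$length <= 0))
    stop("calibration error: non-positive link length", call. = FALSE)
  class(out) <- c("segment_lengths", "data.frame")
  out
}

#' Correct link lengths root-outward
#'
#' The raw stick model supplies proper line orientation but noisy segment
#' sizes. Processing each link sequentially from the root (thoracic segment)
#' to the end joint, every child is repositioned at
#' `parent_corrected + length * unit(child_raw - parent_raw)`: the raw
#' direction is preserved while the link length is pinned to its calibrated
#' reference. If a raw link has zero length in a frame its direction is
#' carried over from the previous frame (an error if it happens in the first
#' frame). The operation is idempotent.
#'
#' @param seq a gap-free [skeleton_sequence()].
#' @param lengths a `segment_lengths` table from
#'   [calibrate_reference_lengths()].
#' @param chain_order `data.frame` of `child,parent` pairs, topologically
#'   sorted root to extremity; defaults to [default_link_chain()].
#' @return A corrected [skeleton_sequence()].
#' @export
correct_link_lengths <- function(seq, lengths,
                                 chain_order = default_link_chain()) {
  validate_sequence(seq)
  key <- paste(chain_order$child, chain_order$parent)
  lkey <- paste(lengths$child, lengths$parent)
  miss <- setdiff(key, lkey)
  if (length(miss) > 0L)
    stop("no calibrated length for link(s): ", paste(miss, collapse = "; "),
         call. = FALSE)
  frames <- seq$frames
  raw <- seq$frames
  n <- dim(frames)[1L]
  for (k in seq_len(nrow(chain_order))) {
    ch <- chain_order$child[k]
    pa <- chain_order$parent[k]
    if (!all(c(ch, pa) %in% seq$joints)) next
    L <- lengths$length[match(paste(ch, pa), lkey)]
    d <- raw[, ch, ] - raw[, pa, ]
    if (n == 1L) dim(d) <- c(1L, 3L)
    nn <- rows_norm(d)
    zero <- nn < 1e-12
    if (any(zero)) {
      if (zero[1L])
        stop("zero-length raw link ", ch, "-", pa,
             " in first frame: direction undefined", call. = FALSE)
      for (i in which(zero)) {
        d[i, ] <- d[i - 1L, ]
        nn[i] <- nn[i - 1L]
      }
    }
    frames[, ch, ] <- frames[, pa, ] + L * d / nn
  }
  out <- seq
  out$frames <- frames
  out
}

.lcs_point <- function(seq, a, b) {
  pa <- joint_xyz(seq, a)
  if (is.na(b) || !nzchar(b)) return(pa)
  (pa + joint_xyz(seq, b)) / 2
}

#' Build segment local coordinate systems
#'
#' Constructs, per frame, the origin and right-handed orthonormal orientation
#' of each LCS in the convention table (19 LCSs in the shipped default, with
#' axis orientations following ISB-style recommendations: Y longitudinal
#' distal-to-proximal, X anterior, Z = X x Y). A frame in which an LCS's
#' defining vectors are (near-)parallel or zero makes the triad undefined and
#' raises an error naming the LCS.
#'
#' @param seq a gap-free [skeleton_sequence()] containing the joints each LCS
#'   requires.
#' @param convention LCS construction table, see [default_lcs_convention()].
#' @return An `lcs_frame_set`: list with `ids`, `names`, `origins`
#'   (`N x L x 3`, metres, global frame) and `rotations` (`3 x 3 x L x N`,
#'   columns are the local axes expressed in the global frame), `frequency`.
#' @export
build_lcs <- function(seq, convention = default_lcs_convention()) {
  validate_sequence(seq)
  n <- n_frames(seq)
  L <- nrow(convention)
  need <- unique(unlist(convention[, c("origin_a", "y_from", "y_to",
                                       "w_from", "w_to")]))
  need <- c(need, convention$origin_b[nzchar(convention$origin_b)])
  miss <- setdiff(need[nzchar(need)], seq$joints)
  if (length(miss) > 0L) {
    bad <- convention$lcs_id[apply(convention, 1L, function(r)
      any(r[c("origin_a", "origin_b", "y_from", "y_to", "w_from", "w_to")]
          %in% miss))]
    stop("model error: joints missing for LCS id(s) ",
         paste(bad, collapse = ", "), ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  origins <- array(NA_real_, c(n, L, 3L))
  rotations <- array(NA_real_, c(3L, 3L, L, n))
  for (k in seq_len(L)) {
    origins[, k, ] <- .lcs_point(seq, convention$origin_a[k],
                                 convention$origin_b[k])
    yv <- joint_xyz(seq, convention$y_to[k]) -
      joint_xyz(seq, convention$y_from[k])
    wv <- joint_xyz(seq, convention$w_to[k]) -
      joint_xyz(seq, convention$w_from[k])
    ny <- rows_norm(yv)
    if (any(ny < 1e-9))
      stop("model error: degenerate longitudinal axis for LCS ",
           convention$lcs_id[k], " ('", convention$name[k], "') at frame ",
           which(ny < 1e-9)[1L], call. = FALSE)
    yv <- yv / ny
    xv <- rows_cross(yv, wv)
    nx <- rows_norm(xv)
    if (any(nx < 1e-9))
      stop("model error: coincident defining directions for LCS ",
           convention$lcs_id[k], " ('", convention$name[k], "') at frame ",
           which(nx < 1e-9)[1L], call. = FALSE)
    xv <- xv / nx
    zv <- rows_cross(xv, yv)
    for (i in seq_len(n))
      rotations[, , k, i] <- cbind(xv[i, ], yv[i, ], zv[i, ])
  }
  structure(list(ids = convention$lcs_id, names = convention$name,
                 origins = origins, rotations = rotations,
                 frequency = seq$frequency, n = n),
            class = "lcs_frame_set")
}

#' @export
print.lcs_frame_set <- function(x, ...) {
  cat(sprintf("lcs_frame_set: %d LCS x %d frames @ %g Hz\n",
              length(x$ids), x$n, x$frequency))
  invisible(x)
}

#' Construct a relative trajectory
#'
#' An `N x 3` sequence of one child LCS origin expressed in its parent LCS,
#' sampled at a fixed frequency: the raw material for the 41 trajectory-shape
#' parameters.
#'
#' @param points numeric `N x 3` matrix, metres, parent-LCS coordinates.
#' @param frequency sampling frequency in Hz.
#' @param label trajectory label, e.g. `"elbow_l_in_girdle_l"`.
#' @param motion_id integer motion id from the topology table.
#' @return An object of class `relative_trajectory`.
#' @export
relative_trajectory <- function(points, frequency, label = "",
                                motion_id = NA_integer_) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, frequency > 0)
  if (!all(is.finite(points)))
    stop("relative trajectory contains non-finite coordinates", call. = FALSE)
  structure(list(label = label, motion_id = as.integer(motion_id),
                 points = unname(points), frequency = frequency),
            class = "relative_trajectory")
}

#' @export
print.relative_trajectory <- function(x, ...) {
  cat(sprintf("relative_trajectory '%s' (motion %s): %d points @ %g Hz\n",
              x$label, x$motion_id, nrow(x$points), x$frequency))
  invisible(x)
}

#' Extract child-in-parent relative trajectories
#'
#' For every topology entry, the child LCS origin is expressed per frame in
#' its parent LCS: `p_i = R_parent^T (origin_child - origin_parent)`. Parent
#' id 0 leaves global coordinates unchanged. The shipped default topology
#' yields exactly 17 trajectories. Relative trajectories are invariant under
#' rigid transforms of the whole global-frame sequence.
#'
#' @param lcs an `lcs_frame_set` from [build_lcs()].
#' @param topo topology table, see [default_topology()].
#' @return A named list of [relative_trajectory()] objects.
#' @export
extract_relative_trajectories <- function(lcs, topo = default_topology()) {
  stopifnot(inherits(lcs, "lcs_frame_set"))
  ids <- unique(c(topo$child, topo$parent[topo$parent != 0L]))
  miss <- setdiff(ids, lcs$ids)
  if (length(miss) > 0L)
    stop("topology point id(s) not present in LCS set: ",
         paste(miss, collapse = ", "), call. = FALSE)
  n <- lcs$n
  out <- vector("list", nrow(topo))
  for (k in seq_len(nrow(topo))) {
    ci <- match(topo$child[k], lcs$ids)
    if (topo$parent[k] == 0L) {
      pts <- matrix(lcs$origins[, ci, ], n, 3L)
      pname <- "global"
    } else {
      pi <- match(topo$parent[k], lcs$ids)
      d <- matrix(lcs$origins[, ci, ] - lcs$origins[, pi, ], n, 3L)
      pts <- matrix(NA_real_, n, 3L)
      for (i in seq_len(n))
        pts[i, ] <- crossprod(lcs$rotations[, , pi, i], d[i, ])
      pname <- lcs$names[pi]
    }
    lab <- paste0(lcs$names[ci], "_in_", pname)
    out[[k]] <- relative_trajectory(pts, lcs$frequency, label = lab,
                                    motion_id = topo$motion[k])
  }
  names(out) <- vapply(out, `[[`, "", "label")
  out
}

#' Mirror a trajectory label between sides
#'
#' Swaps the `_l`/`_r` side tokens in a trajectory label, used when pairing
#' affected and unaffected limbs.
#'
#' @param label character vector of trajectory labels.
#' @return Labels with sides exchanged.
#' @export
mirror_label <- function(label) {
  tmp <- gsub("_l(?=$|_)", "_@", label, perl = TRUE)
  tmp <- gsub("_r(?=$|_)", "_l", tmp, perl = TRUE)
  gsub("_@", "_r", tmp, fixed = TRUE)
}
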