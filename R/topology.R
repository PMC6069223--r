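#' Default relative-coordinate-system topology for upper-limb assessment
#'
#' The shipped topology table lists 17 motions: each row names a child local
#' coordinate system (LCS) whose origin trajectory is expressed in its parent
#' LCS. Point id 0 denotes the global coordinate system. The induced
#' child/parent graph is acyclic.
#'
#' @param path optional CSV with columns `motion,child,parent` to replace the
#'   shipped default.
#' @return A `data.frame` with columns `motion`, `child`, `parent`.
#' @export
default_topology <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "topology_upper_limb.csv",
                        package = "trajkin", mustWork = TRUE)
  topo <- utils::read.csv(path)
  validate_topology(topo)
}

#' @rdname default_topology
#' @param topo a topology `data.frame`.
#' @export
validate_topology <- function(topo) {
  need <- c("motion", "child", "parent")
  if (!all(need %in% names(topo)))
    stop("topology needs columns motion,child,parent", call. = FALSE)
  if (anyDuplicated(topo$motion))
    stop("duplicate motion ids in topology", call. = FALSE)
  # acyclicity over non-zero ids by repeated leaf stripping
  e <- topo[topo$parent != 0L, c("child", "parent")]
  nodes <- unique(c(e$child, e$parent))
  repeat {
    leaves <- setdiff(nodes, e$parent)
    leaves <- intersect(leaves, nodes)
    if (length(leaves) == 0L) break
    e <- e[!(e$child %in% leaves), , drop = FALSE]
    nodes <- setdiff(nodes, leaves)
  }
  if (nrow(e) > 0L)
    stop("topology contains a cycle", call. = FALSE)
  topo
}

#' Default local-coordinate-system construction table
#'
#' Defines how each of the 19 segment LCSs is built from the 20-joint Kinect
#' skeleton. Per LCS: the origin is `origin_a` (or the midpoint of
#' `origin_a`/`origin_b` when both are given); the longitudinal Y axis points
#' from `y_from` to `y_to` (distal to proximal); a plane-reference vector W
#' runs from `w_from` to `w_to`; then X = unit(Y x W) and Z = X x Y complete a
#' right-handed orthonormal triad. The mapping of point numbers to joints is
#' configuration data, not code: the source publication's figure numbering is
#' ambiguous, so alternative mappings (or the 25-joint Kinect One set) can be
#' supplied as a CSV with the same columns.
#'
#' @param path optional CSV replacing the shipped default.
#' @return A `data.frame` with columns `lcs_id,name,origin_a,origin_b,y_from,
#'   y_to,w_from,w_to`.
#' @export
default_lcs_convention <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lcs_convention_kinect20.csv",
                        package = "trajkin", mustWork = TRUE)
  conv <- utils::read.csv(path, colClasses = "character")
  conv$lcs_id <- as.integer(conv$lcs_id)
  need <- c("lcs_id", "name", "origin_a", "origin_b", "y_from", "y_to",
            "w_from", "w_to")
  if (!all(need %in% names(conv)))
    stop("LCS convention needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  conv
}

#' Default upper-limb link chains for length correction
#'
#' Root-outward ordering of (child, parent) joint pairs along each arm,
#' starting at the thoracic segment, used by [correct_link_lengths()] and
#' [calibrate_reference_lengths()].
#'
#' @return A `data.frame` with columns `child`, `parent`, topologically sorted
#'   root to extremity.
#' @export
default_link_chain <- function() {
  data.frame(
    child  = c("spine", "shoulder_center",
               "shoulder_l", "elbow_l", "wrist_l", "hand_l",
               "shoulder_r", "elbow_r", "wrist_r", "hand_r"),
    parent = c("hip_center", "spine",
               "shoulder_center", "shoulder_l", "elbow_l", "wrist_l",
               "shoulder_center", "shoulder_r", "elbow_r", "wrist_r"),
    stringsAsFactors = FALSE)
}
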