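#' Kinect v1 joint vocabulary
#'
#' The 20 joint labels of the first-generation Kinect skeleton, in SDK order.
#' Stored as data rather than hard-coded so that other vocabularies (e.g. the
#' 25-joint Kinect One set) can be supplied to the readers.
#'
#' @return Character vector of 20 joint labels.
#' @export
kinect20_joints <- function() {
  c("hip_center", "spine", "shoulder_center", "head",
    "shoulder_l", "elbow_l", "wrist_l", "hand_l",
    "shoulder_r", "elbow_r", "wrist_r", "hand_r",
    "hip_l", "knee_l", "ankle_l", "foot_l",
    "hip_r", "knee_r", "ankle_r", "foot_r")
}

# Common alternative spellings mapped onto the canonical vocabulary.
.joint_aliases <- local({
  canon <- c("hip_center", "spine", "shoulder_center", "head",
             "shoulder_l", "elbow_l", "wrist_l", "hand_l",
             "shoulder_r", "elbow_r", "wrist_r", "hand_r",
             "hip_l", "knee_l", "ankle_l", "foot_l",
             "hip_r", "knee_r", "ankle_r", "foot_r")
  alias <- c(HipCenter = "hip_center", Spine = "spine",
             ShoulderCenter = "shoulder_center", Head = "head",
             ShoulderLeft = "shoulder_l", ElbowLeft = "elbow_l",
             WristLeft = "wrist_l", HandLeft = "hand_l",
             ShoulderRight = "shoulder_r", ElbowRight = "elbow_r",
             WristRight = "wrist_r", HandRight = "hand_r",
             HipLeft = "hip_l", KneeLeft = "knee_l", AnkleLeft = "ankle_l",
             FootLeft = "foot_l", HipRight = "hip_r", KneeRight = "knee_r",
             AnkleRight = "ankle_r", FootRight = "foot_r")
  c(stats::setNames(canon, canon), alias)
})

normalize_joint_labels <- function(labels) {
  out <- labels
  hit <- labels %in% names(.joint_aliases)
  out[hit] <- unname(.joint_aliases[labels[hit]])
  unknown <- setdiff(unique(out), kinect20_joints())
  if (length(unknown) > 0L)
    warning("unknown joint labels retained as-is: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  out
}

#' Construct a skeleton sequence
#'
#' A `skeleton_sequence` holds a time-ordered stream of labelled 3D joint
#' positions sampled at a fixed frequency. Positions are stored in metres in
#' the global (camera) coordinate system as an `N x J x 3` array, where frame
#' `i` is taken at time `(i - 1) / frequency`.
#'
#' @param frames numeric `N x J x 3` array of positions in metres (dimensions
#'   frame, joint, coordinate).
#' @param joints character vector of `J` joint labels.
#' @param frequency sampling frequency in Hz (> 0).
#' @param subject_id optional subject identifier.
#' @param meta optional named list of free-form metadata.
#' @param allow_na logical; if `FALSE` (default) any missing position is an
#'   error. Readers set `TRUE` and expect [fill_gaps()] to be applied.
#' @return An object of class `skeleton_sequence`.
#' @seealso [read_sequence()], [fill_gaps()], [resample_sequence()]
#' @export
skeleton_sequence <- function(frames, joints, frequency, subject_id = "",
                              meta = list(), allow_na = FALSE) {
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency <= 0)
    stop("frequency must be a single positive number", call. = FALSE)
  frames <- as.array(frames)
  if (length(dim(frames)) != 3L || dim(frames)[3L] != 3L)
    stop("frames must be an N x J x 3 array", call. = FALSE)
  if (dim(frames)[1L] < 1L || dim(frames)[2L] < 1L)
    stop("need at least one frame and one joint", call. = FALSE)
  joints <- as.character(joints)
  if (length(joints) != dim(frames)[2L])
    stop("length(joints) must match dim(frames)[2]", call. = FALSE)
  if (anyDuplicated(joints))
    stop("duplicate joint labels", call. = FALSE)
  if (!allow_na && anyNA(frames))
    stop("frames contain missing positions; apply fill_gaps() first",
         call. = FALSE)
  dimnames(frames) <- list(NULL, joints, c("x", "y", "z"))
  structure(list(frequency = frequency, joints = joints, frames = frames,
                 subject_id = as.character(subject_id), meta = meta),
            class = "skeleton_sequence")
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf("skeleton_sequence: %d frames x %d joints @ %g Hz (%.2f s)\n",
              n_frames(x), length(x$joints), x$frequency,
              n_frames(x) / x$frequency))
  if (nzchar(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  invisible(x)
}

#' Number of frames in a skeleton sequence
#' @param seq a [skeleton_sequence()].
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$frames)[1L]

#' Frame times of a skeleton sequence
#' @param seq a [skeleton_sequence()].
#' @return Numeric vector of times in seconds (frame i at `(i-1)/frequency`).
#' @export
frame_times <- function(seq) (seq_len(n_frames(seq)) - 1L) / seq$frequency

#' Positions of one joint across frames
#' @param seq a [skeleton_sequence()].
#' @param joint joint label.
#' @return `N x 3` matrix in metres.
#' @export
joint_xyz <- function(seq, joint) {
  if (!joint %in% seq$joints)
    stop("joint not present in sequence: ", joint, call. = FALSE)
  m <- seq$frames[, joint, , drop = FALSE]
  dim(m) <- c(dim(seq$frames)[1L], 3L)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Validate a skeleton sequence
#'
#' Checks the container invariants: positive frequency, at least one frame and
#' joint, no missing or non-finite positions.
#'
#' @param seq a [skeleton_sequence()].
#' @return `seq`, invisibly; stops on violation.
#' @export
validate_sequence <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (seq$frequency <= 0) stop("frequency must be > 0", call. = FALSE)
  if (anyNA(seq$frames) || !all(is.finite(seq$frames)))
    stop("sequence contains missing or non-finite positions", call. = FALSE)
  invisible(seq)
}
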