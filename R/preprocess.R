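#' Fill short tracking gaps by linear interpolation
#'
#' Depth-camera trackers intermittently lose joints; short runs of missing
#' samples are filled per joint and coordinate by linear interpolation in
#' time. Runs longer than `max_gap` frames (and gaps touching the first or
#' last frame, which cannot be interpolated) raise a data-quality error naming
#' the joint and frame range.
#'
#' @param seq a [skeleton_sequence()] possibly containing `NA` positions.
#' @param max_gap maximum run length (frames) that may be interpolated;
#'   default 5 frames (~0.17 s at 30 Hz).
#' @return A gap-free [skeleton_sequence()].
#' @export
fill_gaps <- function(seq, max_gap = 5L) {
  stopifnot(inherits(seq, "skeleton_sequence"), max_gap >= 0)
  frames <- seq$frames
  n <- dim(frames)[1L]
  for (j in seq_along(seq$joints)) {
    # a joint sample is missing if any coordinate is NA
    miss <- apply(is.na(frames[, j, , drop = FALSE]), 1L, any)
    if (!any(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      bad <- r$lengths[k] > max_gap || starts[k] == 1L || ends[k] == n
      if (bad)
        stop(sprintf(
          "data-quality error: joint '%s' missing for frames %d-%d (max_gap=%d)",
          seq$joints[j], starts[k], ends[k], max_gap), call. = FALSE)
    }
    idx <- seq_len(n)
    for (c in 1:3) {
      v <- frames[, j, c]
      frames[, j, c] <- stats::approx(idx[!miss], v[!miss], xout = idx,
                                      method = "linear")$y
    }
  }
  out <- seq
  out$frames <- frames
  validate_sequence(out)
  out
}

#' Resample a skeleton sequence to a new frequency
#'
#' Linear time-interpolation of every coordinate onto a regular grid at
#' `target_frequency`, e.g. to bring a 90 Hz optoelectronic stream down to the
#' 30 Hz of a depth camera for paired comparison. Duration is preserved to
#' within one sample period; resampling at the native frequency is the
#' identity.
#'
#' @param seq a gap-free [skeleton_sequence()] with at least 2 frames.
#' @param target_frequency new sampling frequency in Hz (> 0).
#' @return A [skeleton_sequence()] at `target_frequency`.
#' @export
resample_sequence <- function(seq, target_frequency) {
  stopifnot(inherits(seq, "skeleton_sequence"), target_frequency > 0)
  validate_sequence(seq)
  n <- n_frames(seq)
  if (n < 2L) stop("cannot resample a sequence with fewer than 2 frames",
                   call. = FALSE)
  t_old <- frame_times(seq)
  t_end <- t_old[n]
  n_new <- floor(t_end * target_frequency + 1e-9) + 1L
  t_new <- (seq_len(n_new) - 1L) / target_frequency
  J <- length(seq$joints)
  frames <- array(NA_real_, c(n_new, J, 3L))
  for (j in seq_len(J))
    for (c in 1:3)
      frames[, j, c] <- stats::approx(t_old, seq$frames[, j, c],
                                      xout = t_new, method = "linear")$y
  skeleton_sequence(frames, seq$joints, target_frequency,
                    subject_id = seq$subject_id, meta = seq$meta)
}
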