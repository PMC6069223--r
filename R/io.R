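#' Read a skeleton stream from a text file
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`csv-long`}{columns `frame,time_s,joint,x,y,z`; one row per joint
#'     per frame; header mandatory, UTF-8, "." decimal.}
#'   \item{`csv-wide`}{columns `frame,time_s` followed by
#'     `x_<joint>,y_<joint>,z_<joint>` triplets.}
#'   \item{`json`}{object `{frequency, joints, frames}` where `frames` is an
#'     array of frames, each an array of `[x, y, z]` triplets in joint order.}
#' }
#' The sampling frequency of the CSV dialects is inferred from the `time_s`
#' column, which must be on a regular grid. Missing samples may be encoded as
#' empty fields or the literal `NaN`/`NA`; apply [fill_gaps()] before analysis.
#'
#' @param path file path.
#' @param dialect one of `"csv-long"`, `"csv-wide"`, `"json"`.
#' @param units unit of the stored coordinates (`"m"`, `"cm"` or `"mm"`);
#'   positions are converted to metres internally.
#' @param subject_id optional subject identifier attached to the result.
#' @return A validated [skeleton_sequence()] (possibly still containing gaps).
#' @export
read_sequence <- function(path, dialect = c("csv-long", "csv-wide", "json"),
                          units = c("m", "cm", "mm"), subject_id = "") {
  dialect <- match.arg(dialect)
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  scale <- switch(units, m = 1, cm = 0.01, mm = 0.001)
  seq <- switch(dialect,
                "csv-long" = .read_csv_long(path),
                "csv-wide" = .read_csv_wide(path),
                "json" = .read_json_seq(path))
  seq$frames <- seq$frames * scale
  seq$subject_id <- as.character(subject_id)
  seq
}

.infer_frequency <- function(time_s, path) {
  t <- sort(unique(time_s))
  if (length(t) < 2L) return(30)          # single frame: frequency unknowable
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6 * max(dt, 1e-9))
    stop("format error in ", path, ": mixed frame frequencies (irregular ",
         "time_s grid); resample externally or supply json with a frequency",
         call. = FALSE)
  1 / stats::median(dt)
}

.num_or_die <- function(x, what, path, line_of) {
  x <- trimws(x)
  x[x == "" | toupper(x) %in% c("NA", "NAN")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0L)
    stop("parse error in ", path, " line ", line_of(bad[1L]),
         ": non-numeric ", what, " value '", x[bad[1L]], "'", call. = FALSE)
  out
}

.read_csv_long <- function(path) {
  d <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8",
                       check.names = FALSE)
  need <- c("frame", "time_s", "joint", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("format error in ", path, ": csv-long needs columns ",
         paste(need, collapse = ","), call. = FALSE)
  line_of <- function(i) i + 1L  # + header
  fr <- .num_or_die(d$frame, "frame", path, line_of)
  ts <- .num_or_die(d$time_s, "time_s", path, line_of)
  xyz <- vapply(c("x", "y", "z"),
                function(cc) .num_or_die(d[[cc]], cc, path, line_of),
                numeric(nrow(d)))
  if (anyNA(fr)) stop("parse error in ", path, ": missing frame index",
                      call. = FALSE)
  joints <- normalize_joint_labels(d$joint)
  ujoints <- unique(joints)
  ufr <- sort(unique(fr))
  n <- length(ufr)
  frames <- array(NA_real_, c(n, length(ujoints), 3L))
  fi <- match(fr, ufr)
  ji <- match(joints, ujoints)
  for (k in 1:3) frames[cbind(fi, ji, k)] <- xyz[, k]
  freq <- .infer_frequency(ts[!is.na(ts)], path)
  skeleton_sequence(frames, ujoints, freq, allow_na = TRUE)
}

.read_csv_wide <- function(path) {
  d <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8",
                       check.names = FALSE)
  if (!all(c("frame", "time_s") %in% names(d)))
    stop("format error in ", path, ": csv-wide needs frame,time_s", call. = FALSE)
  cc <- setdiff(names(d), c("frame", "time_s"))
  m <- regmatches(cc, regexec("^([xyz])_(.+)$", cc))
  ok <- lengths(m) == 3L
  if (!all(ok))
    stop("format error in ", path, ": unrecognized column '", cc[!ok][1L], "'",
         call. = FALSE)
  ax <- vapply(m, `[`, "", 2L)
  jn <- vapply(m, `[`, "", 3L)
  joints <- unique(jn)
  for (j in joints)
    if (!setequal(ax[jn == j], c("x", "y", "z")))
      stop("format error in ", path, ": incomplete x/y/z triplet for joint ", j,
           call. = FALSE)
  line_of <- function(i) i + 1L
  ts <- .num_or_die(d$time_s, "time_s", path, line_of)
  n <- nrow(d)
  joints_norm <- normalize_joint_labels(joints)
  frames <- array(NA_real_, c(n, length(joints), 3L))
  for (k in seq_along(cc)) {
    v <- .num_or_die(d[[cc[k]]], cc[k], path, line_of)
    frames[, match(jn[k], joints), match(ax[k], c("x", "y", "z"))] <- v
  }
  freq <- .infer_frequency(ts[!is.na(ts)], path)
  skeleton_sequence(frames, joints_norm, freq, allow_na = TRUE)
}

.read_json_seq <- function(path) {
  o <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(o$frequency) || is.null(o$joints) || is.null(o$frames))
    stop("format error in ", path, ": json needs frequency, joints, frames",
         call. = FALSE)
  joints <- normalize_joint_labels(as.character(o$joints))
  fr <- o$frames  # simplifies to N x J x 3 when rectangular
  if (is.list(fr)) fr <- simplify2array(fr)
  frames <- array(as.numeric(fr), dim = dim(fr))
  if (length(dim(frames)) != 3L)
    stop("format error in ", path, ": frames is not rectangular", call. = FALSE)
  skeleton_sequence(frames, joints, o$frequency,
                    subject_id = o$subject_id %||% "",
                    meta = as.list(o$meta %||% list()), allow_na = TRUE)
}

#' Write a skeleton stream to a text file
#'
#' @inheritParams read_sequence
#' @param seq a [skeleton_sequence()].
#' @param digits significant digits written in CSV dialects (default preserves
#'   positions to well below 1e-6 m).
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path,
                           dialect = c("csv-long", "csv-wide", "json"),
                           digits = 9) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(seq, "skeleton_sequence"))
  n <- n_frames(seq)
  tt <- frame_times(seq)
  if (dialect == "json") {
    o <- list(frequency = seq$frequency, joints = seq$joints,
              subject_id = seq$subject_id, meta = seq$meta,
              frames = lapply(seq_len(n), function(i) {
                m <- seq$frames[i, , , drop = FALSE]
                dim(m) <- c(length(seq$joints), 3L)
                m
              }))
    jsonlite::write_json(o, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  # frame times get extra digits so the frequency survives the round trip
  fmt_t <- function(v) formatC(v, digits = 13, format = "g")
  if (dialect == "csv-long") {
    J <- length(seq$joints)
    d <- data.frame(frame = rep(seq_len(n), each = J),
                    time_s = rep(fmt_t(tt), each = J),
                    joint = rep(seq$joints, n),
                    x = fmt(as.vector(t(seq$frames[, , 1L]))),
                    y = fmt(as.vector(t(seq$frames[, , 2L]))),
                    z = fmt(as.vector(t(seq$frames[, , 3L]))))
  } else {
    d <- data.frame(frame = seq_len(n), time_s = fmt_t(tt))
    for (j in seq$joints)
      for (k in 1:3)
        d[[paste0(c("x", "y", "z")[k], "_", j)]] <- fmt(seq$frames[, j, k])
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference parameter table
#'
#' Reference (control-group) feature statistics used for scoring: CSV with
#' columns `group,trajectory,param_index,param_name,mean,std,unit`.
#'
#' @param path file path.
#' @return A `data.frame` with those columns, validated (`param_index` in
#'   1..41, `std >= 0`).
#' @export
read_reference_table <- function(path) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("group", "trajectory", "param_index", "param_name", "mean", "std",
            "unit")
  if (!all(need %in% names(d)))
    stop("reference table needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  validate_reference_table(d)
}

#' @rdname read_reference_table
#' @param ref a reference table `data.frame`.
#' @export
validate_reference_table <- function(ref) {
  if (!all(ref$param_index %in% 1:41))
    stop("reference table param_index values must lie in 1..41", call. = FALSE)
  if (any(!is.na(ref$std) & ref$std < 0))
    stop("reference table dispersions must be >= 0", call. = FALSE)
  ref
}

#' @rdname read_reference_table
#' @export
write_reference_table <- function(ref, path) {
  utils::write.csv(validate_reference_table(ref), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
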