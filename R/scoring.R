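#' Default 17-parameter visualization panel
#'
#' The star-plot panel groups 17 of the 41 parameters into angular (Ang,
#' n = 6), length (Len, n = 6) and volumetric (Vol, n = 5) characteristics.
#' The published method does not enumerate the panel membership, so this is a
#' package default shipped as an editable CSV asset: Ang = {2, 6, 9, 12, 13,
#' 40}, Len = {1, 3, 5, 14, 15, 32}, Vol = {10, 11, 31, 38, 39}. Signed
#' coordinate parameters (16-30, 35-37) are excluded by default because ratio
#' scores of signed coordinates are not meaningful; they can be opted in with
#' a custom panel.
#'
#' @param path optional CSV with columns `group,param_index` replacing the
#'   shipped default.
#' @return A `data.frame` with columns `group` (`Ang`/`Len`/`Vol`) and
#'   `param_index`.
#' @export
default_panel <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "panel_default17.csv", package = "trajkin",
                        mustWork = TRUE)
  p <- utils::read.csv(path)
  stopifnot(all(c("group", "param_index") %in% names(p)),
            all(p$param_index %in% 1:41))
  p
}

#' Build a reference table from feature tables
#'
#' Summarises one or more subjects' long feature tables (see
#' [features_table()]) into the reference (control-group) format used for
#' scoring: per (trajectory, parameter), the across-subject mean and standard
#' deviation (0 when a single subject is supplied).
#'
#' @param features a long feature `data.frame` or list of them (one per
#'   subject).
#' @param group reference group label.
#' @return A reference table `data.frame` with columns
#'   `group,trajectory,param_index,param_name,mean,std,unit`.
#' @export
reference_from_features <- function(features, group = "reference") {
  if (is.data.frame(features)) features <- list(features)
  all <- do.call(rbind, Map(function(d, i) cbind(d, .subj = i),
                            features, seq_along(features)))
  key <- interaction(all$trajectory, all$param_index, drop = TRUE)
  agg <- do.call(rbind, lapply(split(all, key), function(d) {
    data.frame(group = group, trajectory = d$trajectory[1L],
               param_index = d$param_index[1L], param_name = d$param_name[1L],
               mean = mean(d$value),
               std = if (nrow(d) > 1L) stats::sd(d$value) else 0,
               unit = d$unit[1L], stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  validate_reference_table(agg)
}

#' Dimensionless parameter scores against a reference
#'
#' The per-parameter score is the ratio `s = reference_mean / patient_value`:
#' a score of 1 (100%) means the patient matches the reference; scores above 1
#' indicate a smaller patient value. The raw ratio is preserved for
#' longitudinal tracking while a display channel clamps scores to
#' `[-1, 1]` (the +/-100% range of the star plot). Zero or missing patient
#' values give undefined scores, which are flagged and excluded from
#' aggregates.
#'
#' @param patient long feature `data.frame` from [features_table()] (or a
#'   single `feature_vector`).
#' @param reference reference table (see [read_reference_table()] /
#'   [reference_from_features()]), covering every (trajectory, parameter)
#'   being scored.
#' @return An object of class `score_card` with a `scores` data frame
#'   (`trajectory,param_index,param_name,score_raw,score_display,flag`).
#' @export
parameter_scores <- function(patient, reference) {
  if (inherits(patient, "feature_vector")) patient <- as.data.frame(patient)
  reference <- validate_reference_table(reference)
  m <- merge(patient, reference, by = c("trajectory", "param_index"),
             suffixes = c("", ".ref"))
  if (nrow(m) < nrow(patient)) {
    missing <- !interaction(patient$trajectory, patient$param_index) %in%
      interaction(reference$trajectory, reference$param_index)
    stop("reference does not cover: ",
         paste(utils::head(paste0(patient$trajectory[missing], "#",
                                  patient$param_index[missing]), 5L),
               collapse = ", "), call. = FALSE)
  }
  raw <- m$mean / m$value
  flag <- ifelse(!is.na(m$flag) & nzchar(m$flag), m$flag, "")
  undef <- is.na(m$value) | m$value == 0 | !is.finite(raw)
  if (any(undef)) {
    warning(sum(undef), " score(s) undefined (zero or missing patient value)",
            call. = FALSE)
    flag[undef] <- trimws(paste(flag[undef], "undefined_score"))
    raw[undef] <- NA_real_
  }
  sc <- data.frame(trajectory = m$trajectory, param_index = m$param_index,
                   param_name = m$param_name, score_raw = raw,
                   score_display = clamp(raw, -1, 1), flag = flag,
                   stringsAsFactors = FALSE)
  sc <- sc[order(sc$trajectory, sc$param_index), ]
  rownames(sc) <- NULL
  structure(list(scores = sc,
                 reference_group = reference$group[1L],
                 aggregates = NULL),
            class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("score_card vs '%s': %d scores over %d trajectories\n",
              x$reference_group, nrow(x$scores),
              length(unique(x$scores$trajectory))))
  if (!is.null(x$aggregates)) {
    cat("  group scores:\n")
    print(x$aggregates$group_scores)
    cat(sprintf("  total score: %.1f%%\n", 100 * x$aggregates$total))
  }
  invisible(x)
}

.weighted_mean <- function(x, w) {
  if (sum(w) <= 0)
    stop("aggregation error: all-zero weights over a selection",
         call. = FALSE)
  keep <- !is.na(x) & w > 0
  if (!any(keep)) return(NA_real_)  # every member undefined: propagate NA
  sum(w[keep] * x[keep]) / sum(w[keep])
}

#' Aggregate parameter scores into trajectory, group and total scores
#'
#' Weighted-mean aggregation of the raw parameter scores: per trajectory over
#' the selected parameters, per star-plot sector over trajectories, per
#' Ang/Len/Vol group over sectors, and a single total score over trajectories.
#' Default weights are all 1 (unweighted means). Aggregates are convex
#' combinations of member scores under nonnegative weights. Flagged
#' (undefined) scores are excluded.
#'
#' @param card a `score_card` from [parameter_scores()].
#' @param panel parameter selection with columns `group,param_index`; defaults
#'   to [default_panel()].
#' @param param_weights optional `data.frame(param_index, weight)` (optionally
#'   also `trajectory`) of nonnegative per-parameter weights.
#' @param trajectory_weights optional `data.frame(trajectory, weight)`.
#' @return The `score_card` with an `aggregates` list: `per_trajectory`
#'   (trajectory scores S_pj), `sectors` (per-panel-parameter scores across
#'   trajectories), `group_scores` (Ang/Len/Vol), `total` (the overall
#'   weighted score C_p, 1 = 100%).
#' @export
aggregate_scores <- function(card, panel = default_panel(),
                             param_weights = NULL,
                             trajectory_weights = NULL) {
  stopifnot(inherits(card, "score_card"))
  if (nrow(panel) == 0L) stop("empty parameter selection", call. = FALSE)
  sc <- card$scores[card$scores$param_index %in% panel$param_index, ,
                    drop = FALSE]
  if (nrow(sc) == 0L) stop("selection matches no scores", call. = FALSE)
  wp <- rep(1, nrow(sc))
  if (!is.null(param_weights)) {
    if (any(param_weights$weight < 0))
      stop("weights must be nonnegative", call. = FALSE)
    if ("trajectory" %in% names(param_weights))
      wp <- param_weights$weight[match(
        paste(sc$trajectory, sc$param_index),
        paste(param_weights$trajectory, param_weights$param_index))]
    else
      wp <- param_weights$weight[match(sc$param_index,
                                       param_weights$param_index)]
    if (anyNA(wp)) stop("weights do not cover the selection", call. = FALSE)
  }
  x <- sc$score_raw
  x[nzchar(sc$flag) & grepl("undefined_score", sc$flag)] <- NA_real_

  per_traj <- do.call(rbind, lapply(split(seq_len(nrow(sc)), sc$trajectory),
    function(i) data.frame(trajectory = sc$trajectory[i[1L]],
                           score = .weighted_mean(x[i], wp[i]))))
  rownames(per_traj) <- NULL

  sectors <- do.call(rbind, lapply(seq_len(nrow(panel)), function(k) {
    i <- which(sc$param_index == panel$param_index[k])
    data.frame(param_index = panel$param_index[k],
               param_name = feature_definitions()$param_name[
                 panel$param_index[k]],
               group = panel$group[k],
               score = .weighted_mean(x[i], wp[i]))
  }))

  group_scores <- do.call(rbind, lapply(split(sectors, sectors$group),
    function(d) data.frame(group = d$group[1L],
                           score = mean(d$score, na.rm = TRUE),
                           n = nrow(d))))
  rownames(group_scores) <- NULL

  wt <- rep(1, nrow(per_traj))
  if (!is.null(trajectory_weights)) {
    if (any(trajectory_weights$weight < 0))
      stop("weights must be nonnegative", call. = FALSE)
    wt <- trajectory_weights$weight[match(per_traj$trajectory,
                                          trajectory_weights$trajectory)]
    if (anyNA(wt)) stop("trajectory weights do not cover the card",
                        call. = FALSE)
  }
  total <- .weighted_mean(per_traj$score, wt)
  card$aggregates <- list(per_trajectory = per_traj, sectors = sectors,
                          group_scores = group_scores, total = total)
  card
}

#' Joint-angle dimensionless scores
#'
#' The single-joint analogue of [parameter_scores()]: per joint and axis the
#' score is `s = reference_angle / patient_angle`, each joint gets a weighted
#' mean over its x/y/z axes, and the overall angle score is a weighted mean
#' over joints. Zero patient angles are flagged and excluded.
#'
#' @param patient_angles,reference_angles `data.frame`s with columns
#'   `joint,axis,value` and matched joint/axis coverage.
#' @param axis_weights optional `data.frame(joint, axis, weight)`.
#' @param joint_weights optional `data.frame(joint, weight)`.
#' @return A list of class `angle_score_card`: `scores` (per joint/axis),
#'   `joint_scores`, `total`.
#' @export
angle_scores <- function(patient_angles, reference_angles,
                         axis_weights = NULL, joint_weights = NULL) {
  m <- merge(patient_angles, reference_angles, by = c("joint", "axis"),
             suffixes = c(".pt", ".ref"))
  if (nrow(m) != nrow(patient_angles) || nrow(m) != nrow(reference_angles))
    stop("mismatched joint/axis coverage between tables", call. = FALSE)
  s <- m$value.ref / m$value.pt
  flag <- ifelse(m$value.pt == 0 | !is.finite(s), "undefined_score", "")
  s[nzchar(flag)] <- NA_real_
  if (any(nzchar(flag)))
    warning("zero patient angle(s): flagged and excluded", call. = FALSE)
  w <- rep(1, nrow(m))
  if (!is.null(axis_weights)) {
    w <- axis_weights$weight[match(paste(m$joint, m$axis),
                                   paste(axis_weights$joint,
                                         axis_weights$axis))]
    if (anyNA(w) || any(w < 0)) stop("invalid axis weights", call. = FALSE)
  }
  scores <- data.frame(joint = m$joint, axis = m$axis, score = s, flag = flag,
                       stringsAsFactors = FALSE)
  joint_scores <- do.call(rbind, lapply(split(seq_len(nrow(m)), m$joint),
    function(i) data.frame(joint = m$joint[i[1L]],
                           score = .weighted_mean(s[i], w[i]))))
  rownames(joint_scores) <- NULL
  wj <- rep(1, nrow(joint_scores))
  if (!is.null(joint_weights)) {
    wj <- joint_weights$weight[match(joint_scores$joint, joint_weights$joint)]
    if (anyNA(wj) || any(wj < 0)) stop("invalid joint weights", call. = FALSE)
  }
  structure(list(scores = scores, joint_scores = joint_scores,
                 total = .weighted_mean(joint_scores$score, wj)),
            class = "angle_score_card")
}

#' Score the affected limb against the contralateral one
#'
#' For asymmetric conditions (e.g. hemiplegia) the unaffected limb can serve
#' as the reference: the affected side's features are scored against the
#' healthy side's values for the mirrored trajectory labels. Swapping the two
#' sides inverts every raw score (`s -> 1/s`).
#'
#' @param affected,healthy long feature `data.frame`s ([features_table()]) for
#'   the affected and unaffected sides; labels must pair under
#'   [mirror_label()].
#' @return A `score_card` (see [parameter_scores()]).
#' @export
contralateral_reference <- function(affected, healthy) {
  hl <- unique(healthy$trajectory)
  need <- unique(mirror_label(affected$trajectory))
  if (!all(need %in% hl))
    stop("pairing error: no contralateral trajectory for ",
         paste(setdiff(need, hl), collapse = ", "), call. = FALSE)
  ref <- healthy
  ref$trajectory <- mirror_label(ref$trajectory)
  ref <- data.frame(group = "contralateral", trajectory = ref$trajectory,
                    param_index = ref$param_index,
                    param_name = ref$param_name, mean = ref$value,
                    std = 0, unit = ref$unit, stringsAsFactors = FALSE)
  parameter_scores(affected, ref)
}

#' Export star-plot data
#'
#' Serialises an aggregated score card as the deterministic sector list drawn
#' by the star plot: one sector per panel parameter (ordered Ang, Len, Vol,
#' then by parameter index) with its display score in `[-1, 1]`, the Ang/Len/
#' Vol group means, and the total score at the centre. The 100% contour
#' corresponds to a score of 1.
#'
#' @param card an aggregated `score_card` (see [aggregate_scores()]).
#' @param path optional output path; `.json` is written with [jsonlite].
#' @return A list with `sectors`, `groups`, `total` (invisibly if `path` is
#'   given).
#' @export
star_plot_export <- function(card, path = NULL) {
  stopifnot(inherits(card, "score_card"))
  if (is.null(card$aggregates))
    stop("card is not aggregated; run aggregate_scores() first", call. = FALSE)
  s <- card$aggregates$sectors
  if (nrow(s) == 0L) stop("empty selection", call. = FALSE)
  s <- s[order(factor(s$group, levels = c("Ang", "Len", "Vol")),
               s$param_index), ]
  sectors <- data.frame(label = s$param_name, group = s$group,
                        score_display = clamp(s$score, -1, 1),
                        radius = clamp(s$score, -1, 1),
                        stringsAsFactors = FALSE)
  out <- list(sectors = sectors, groups = card$aggregates$group_scores,
              total = card$aggregates$total)
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(out))
  }
  out
}

#' Draw the star plot of an aggregated score card
#'
#' One sector per panel parameter, radius proportional to the display score,
#' coloured by Ang/Len/Vol group, with the 100% reference contour.
#' Requires ggplot2.
#'
#' @param card an aggregated `score_card`.
#' @return A ggplot object.
#' @export
plot_star <- function(card) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_star() requires the ggplot2 package", call. = FALSE)
  d <- star_plot_export(card)$sectors
  d$label <- factor(d$label, levels = d$label)
  ggplot2::ggplot(d, ggplot2::aes(x = label, y = radius, fill = group)) +
    ggplot2::geom_col(width = 1, colour = "grey30") +
    ggplot2::geom_hline(yintercept = 1, colour = "gold", linewidth = 1) +
    ggplot2::coord_polar() +
    ggplot2::scale_fill_manual(values = c(Ang = "#d1495b", Len = "#1f6fb2",
                                          Vol = "#2e8b57")) +
    ggplot2::labs(y = "score (1 = 100%)", x = NULL,
                  title = sprintf("total score %.0f%%",
                                  100 * card$aggregates$total)) +
    ggplot2::theme_minimal()
}
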