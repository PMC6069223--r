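# Seeded generator of Kinect-like skeleton streams emulating a wiping
# rehabilitation exercise (mediolateral and inferior-superior wrist
# displacements relative to the trunk), so the whole pipeline is testable
# without recorded data.

# Neutral standing 20-joint skeleton, metres, global frame:
# X anterior, Y up, Z towards the subject's right.
.base_skeleton <- function() {
  rbind(hip_center = c(0, 1.00, 0), spine = c(0, 1.20, 0),
        shoulder_center = c(0, 1.45, 0), head = c(0, 1.65, 0),
        shoulder_l = c(0, 1.40, -0.20), elbow_l = c(0, 1.10, -0.20),
        wrist_l = c(0, 0.85, -0.20), hand_l = c(0, 0.77, -0.20),
        shoulder_r = c(0, 1.40, 0.20), elbow_r = c(0, 1.10, 0.20),
        wrist_r = c(0, 0.85, 0.20), hand_r = c(0, 0.77, 0.20),
        hip_l = c(0, 0.95, -0.10), knee_l = c(0, 0.50, -0.10),
        ankle_l = c(0, 0.08, -0.10), foot_l = c(0.12, 0.02, -0.10),
        hip_r = c(0, 0.95, 0.10), knee_r = c(0, 0.50, 0.10),
        ankle_r = c(0, 0.08, 0.10), foot_r = c(0.12, 0.02, 0.10))
}

#' Synthetic wiping-motion recipe
#'
#' Parameter bundle for [generate_wipe_sequence()]. The wrist follows a
#' Lissajous path in the frontal plane relative to the (static) trunk:
#' mediolateral displacement `A_ml * sin(2 pi f_ml t)` and inferior-superior
#' displacement `A_is * sin(2 pi f_is t + phase)`, plus i.i.d. Gaussian depth
#' noise on the wrist target. `speed_scale` multiplies both path frequencies
#' (slower groups traverse the same path more slowly) and `amplitude_scale`
#' shrinks the path. Identical seeds give identical streams.
#'
#' @param duration trial length in seconds (default 60 s, a typical
#'   rehabilitation mini-game).
#' @param frequency sampling frequency in Hz (default 30, first-generation
#'   Kinect).
#' @param amp_ml,amp_is mediolateral / inferior-superior wrist amplitudes (m).
#' @param freq_ml,freq_is path frequencies (Hz).
#' @param phase phase offset of the inferior-superior component (rad).
#' @param depth_sigma sd of the depth noise on the wrist target (m).
#' @param jitter_sigma sd of the isotropic per-joint sensor jitter (m).
#' @param speed_scale group-level speed multiplier.
#' @param amplitude_scale group-level workspace multiplier.
#' @param upper_arm,forearm segment lengths used by the two-link inverse
#'   kinematics (m).
#' @param seed RNG seed (integer).
#' @return A list of class `motion_recipe`.
#' @export
motion_recipe <- function(duration = 60, frequency = 30,
                          amp_ml = 0.18, amp_is = 0.12,
                          freq_ml = 0.25, freq_is = 0.5, phase = pi / 2,
                          depth_sigma = 0.005, jitter_sigma = 0.005,
                          speed_scale = 1, amplitude_scale = 1,
                          upper_arm = 0.30, forearm = 0.25, seed = 1L) {
  stopifnot(duration > 0, frequency > 0, depth_sigma >= 0, jitter_sigma >= 0,
            speed_scale > 0, amplitude_scale > 0,
            duration * frequency >= 4)
  structure(list(duration = duration, frequency = frequency, amp_ml = amp_ml,
                 amp_is = amp_is, freq_ml = freq_ml, freq_is = freq_is,
                 phase = phase, depth_sigma = depth_sigma,
                 jitter_sigma = jitter_sigma, speed_scale = speed_scale,
                 amplitude_scale = amplitude_scale, upper_arm = upper_arm,
                 forearm = forearm, seed = as.integer(seed)),
            class = "motion_recipe")
}

# two-link inverse kinematics: elbow position for a wrist target,
# bending towards `bend` (global down by default)
.ik_elbow <- function(shoulder, wrist, L1, L2, bend = c(0, -1, 0)) {
  d <- wrist - shoulder
  dist <- vec_norm(d)
  if (dist > L1 + L2 - 1e-9 || dist < abs(L1 - L2) + 1e-9)
    stop("recipe error: wrist target unreachable for arm lengths ",
         sprintf("(|d|=%.3f m, L1=%.2f, L2=%.2f)", dist, L1, L2),
         call. = FALSE)
  dhat <- d / dist
  a1 <- (L1^2 - L2^2 + dist^2) / (2 * dist)
  h <- sqrt(max(L1^2 - a1^2, 0))
  perp <- bend - sum(bend * dhat) * dhat
  if (vec_norm(perp) < 1e-9) {
    alt <- c(1, 0, 0)
    perp <- alt - sum(alt * dhat) * dhat
  }
  shoulder + a1 * dhat + h * perp / vec_norm(perp)
}

#' Generate a synthetic wiping-exercise skeleton stream
#'
#' Trunk, head and lower-limb joints stay static at a neutral standing pose;
#' each wrist follows the recipe's Lissajous path in the frontal plane in
#' front of its shoulder, the elbow is placed by two-link inverse kinematics
#' (downward bend), the hand is extended along the forearm, and i.i.d.
#' Gaussian sensor jitter is added to every joint of every frame.
#' Deterministic under the recipe seed.
#'
#' @param recipe a [motion_recipe()].
#' @return A [skeleton_sequence()] with the recipe and the true segment
#'   lengths in `meta`.
#' @export
generate_wipe_sequence <- function(recipe = motion_recipe()) {
  stopifnot(inherits(recipe, "motion_recipe"))
  set.seed(recipe$seed)
  f <- recipe$frequency
  n <- as.integer(round(recipe$duration * f))
  t <- (seq_len(n) - 1L) / f
  base <- .base_skeleton()
  joints <- rownames(base)
  frames <- array(rep(base, each = n), c(n, nrow(base), 3L))
  ml <- recipe$amplitude_scale * recipe$amp_ml *
    sin(2 * pi * recipe$freq_ml * recipe$speed_scale * t)
  is_ <- recipe$amplitude_scale * recipe$amp_is *
    sin(2 * pi * recipe$freq_is * recipe$speed_scale * t + recipe$phase)
  for (side in c("l", "r")) {
    sh <- base[paste0("shoulder_", side), ]
    centre <- sh + c(0.28, -0.18, 0)
    depth <- stats::rnorm(n, 0, recipe$depth_sigma)
    wrist <- cbind(centre[1L] + depth, centre[2L] + is_, centre[3L] + ml)
    elbow <- t(vapply(seq_len(n), function(i)
      .ik_elbow(sh, wrist[i, ], recipe$upper_arm, recipe$forearm),
      numeric(3)))
    fore <- rows_unit(wrist - elbow)
    hand <- wrist + 0.08 * fore
    frames[, match(paste0("wrist_", side), joints), ] <- wrist
    frames[, match(paste0("elbow_", side), joints), ] <- elbow
    frames[, match(paste0("hand_", side), joints), ] <- hand
  }
  if (recipe$jitter_sigma > 0)
    frames <- frames + stats::rnorm(length(frames), 0, recipe$jitter_sigma)
  skeleton_sequence(frames, joints, f,
                    meta = list(recipe = unclass(recipe),
                                true_lengths = .true_lengths(recipe)))
}

.true_lengths <- function(recipe = motion_recipe()) {
  base <- .base_skeleton()
  links <- default_link_chain()
  len <- vapply(seq_len(nrow(links)), function(k)
    vec_norm(base[links$child[k], ] - base[links$parent[k], ]), numeric(1))
  len[links$child %in% c("elbow_l", "elbow_r")] <- recipe$upper_arm
  len[links$child %in% c("wrist_l", "wrist_r")] <- recipe$forearm
  len[links$child %in% c("hand_l", "hand_r")] <- 0.08
  data.frame(child = links$child, parent = links$parent, length = len,
             stringsAsFactors = FALSE)
}

#' Generate the three static calibration poses
#'
#' Three 3-second, 30 Hz static streams (T-pose with arms lateral, wide pose
#' with arms 45 degrees up-lateral, upright pose with arms down), with
#' optional sensor jitter. The true segment lengths are recorded in each
#' sequence's `meta$true_lengths` for recovery tests.
#'
#' @param seed RNG seed.
#' @param jitter_sigma per-joint Gaussian jitter sd (m), default 0.
#' @param frequency sampling frequency (Hz).
#' @param duration per-pose duration (s).
#' @return A named list of three [skeleton_sequence()] objects
#'   (`t_pose`, `wide_pose`, `upright_pose`).
#' @export
generate_calibration_poses <- function(seed = 1L, jitter_sigma = 0,
                                       frequency = 30, duration = 3) {
  set.seed(seed)
  n <- as.integer(round(duration * frequency))
  base <- .base_skeleton()
  joints <- rownames(base)
  arm_dirs <- list(t_pose = c(0, 0, 1),
                   wide_pose = c(0, sqrt(0.5), sqrt(0.5)),
                   upright_pose = c(0, -1, 0))
  recipe <- motion_recipe(seed = seed)
  out <- lapply(arm_dirs, function(dd) {
    pose <- base
    for (side in c("l", "r")) {
      sgn <- if (side == "l") -1 else 1
      dir <- dd * c(1, 1, sgn)
      sh <- base[paste0("shoulder_", side), ]
      pose[paste0("elbow_", side), ] <- sh + recipe$upper_arm * dir
      pose[paste0("wrist_", side), ] <- sh +
        (recipe$upper_arm + recipe$forearm) * dir
      pose[paste0("hand_", side), ] <- sh +
        (recipe$upper_arm + recipe$forearm + 0.08) * dir
    }
    frames <- array(rep(pose, each = n), c(n, nrow(pose), 3L))
    if (jitter_sigma > 0)
      frames <- frames + stats::rnorm(length(frames), 0, jitter_sigma)
    skeleton_sequence(frames, joints, frequency,
                      meta = list(true_lengths = .true_lengths(recipe)))
  })
  names(out) <- names(arm_dirs)
  out
}

#' Default group recipes for the synthetic clinical cohort
#'
#' Speed ordering healthy adults > elderly > stroke, with group speed scales
#' 1.00 / 0.57 / 0.43 (the ratios of typical wrist velocities of the three
#' populations) and mildly shrinking workspace.
#'
#' @param duration trial length passed to each recipe (s).
#' @return Named list of [motion_recipe()] objects.
#' @export
default_group_recipes <- function(duration = 60) {
  list(adults = motion_recipe(duration = duration, speed_scale = 1.00,
                              amplitude_scale = 1.00),
       elderly = motion_recipe(duration = duration, speed_scale = 0.57,
                               amplitude_scale = 0.90),
       stroke = motion_recipe(duration = duration, speed_scale = 0.43,
                              amplitude_scale = 0.80))
}

#' Generate a synthetic multi-group cohort
#'
#' Draws per-subject recipes around each group's base recipe with seeded
#' lognormal between-subject variability on the speed and amplitude scales
#' (sd 0.15 and 0.10 on the log scale), then generates one wipe sequence per
#' subject.
#'
#' @param recipes named list of per-group base [motion_recipe()]s; defaults to
#'   [default_group_recipes()].
#' @param n_per_group subjects per group (single value or per-group vector),
#'   >= 2.
#' @param seed cohort-level RNG seed.
#' @return A list with `sequences` (list of [skeleton_sequence()]), `groups`
#'   (character vector), `subjects` (ids).
#' @export
generate_cohort <- function(recipes = default_group_recipes(),
                            n_per_group = c(16L, 17L, 10L), seed = 1L) {
  if (length(n_per_group) == 1L)
    n_per_group <- rep(n_per_group, length(recipes))
  stopifnot(length(n_per_group) == length(recipes), all(n_per_group >= 2L))
  set.seed(seed)
  total <- sum(n_per_group)
  subj_seeds <- sample.int(2^31 - 2, total)
  speed_mult <- exp(stats::rnorm(total, 0, 0.15))
  amp_mult <- exp(stats::rnorm(total, 0, 0.10))
  sequences <- vector("list", total)
  groups <- character(total)
  subjects <- character(total)
  k <- 0L
  for (g in seq_along(recipes)) {
    for (i in seq_len(n_per_group[g])) {
      k <- k + 1L
      r <- recipes[[g]]
      r$speed_scale <- r$speed_scale * speed_mult[k]
      r$amplitude_scale <- r$amplitude_scale * amp_mult[k]
      r$seed <- subj_seeds[k]
      s <- generate_wipe_sequence(r)
      s$subject_id <- sprintf("%s_%02d", names(recipes)[g], i)
      sequences[[k]] <- s
      groups[k] <- names(recipes)[g]
      subjects[k] <- s$subject_id
    }
  }
  list(sequences = sequences, groups = groups, subjects = subjects)
}
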