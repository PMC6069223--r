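self_score_card <- function(n_traj = 2, seed = 50, aggregate = TRUE) {
  trajs <- lapply(seq_len(n_traj), function(i)
    random_traj(40, seed = seed + i))
  for (i in seq_len(n_traj)) trajs[[i]]$label <- paste0("traj", i)
  feats <- features_table(trajs)
  ref <- reference_from_features(feats, group = "self")
  card <- parameter_scores(feats, ref)
  if (aggregate) card <- aggregate_scores(card)
  card
}

test_that("scoring a trial against itself gives every score 1 and total 100%", {
  card <- self_score_card()
  expect_true(all(abs(card$scores$score_raw - 1) < 1e-12))
  expect_equal(card$aggregates$total, 1, tolerance = 1e-12)
  expect_true(all(abs(card$aggregates$per_trajectory$score - 1) < 1e-12))
  expect_true(all(abs(card$aggregates$group_scores$score - 1) < 1e-12))
})

test_that("ratio scores follow control/patient with display clamping", {
  pat <- data.frame(trajectory = "t", param_index = c(1, 3),
                    param_name = c("trajectory_length", "velocity_mean"),
                    unit = c("m", "m/s"), value = c(0.1, 0.2), flag = "")
  ref <- data.frame(group = "adults", trajectory = "t", param_index = c(1, 3),
                    param_name = pat$param_name, mean = c(0.2, 0.1),
                    std = 0, unit = pat$unit)
  card <- parameter_scores(pat, ref)
  expect_equal(card$scores$score_raw, c(2.0, 0.5))
  expect_equal(card$scores$score_display, c(1.0, 0.5))
})

test_that("zero patient values are flagged and excluded from aggregates", {
  pat <- data.frame(trajectory = "t", param_index = 1:3,
                    param_name = feature_definitions()$param_name[1:3],
                    unit = "m", value = c(1, 0, 2), flag = "")
  ref <- data.frame(group = "adults", trajectory = "t", param_index = 1:3,
                    param_name = pat$param_name, mean = c(1, 1, 2), std = 0,
                    unit = "m")
  expect_warning(card <- parameter_scores(pat, ref), "undefined")
  expect_true(is.na(card$scores$score_raw[2]))
  agg <- aggregate_scores(card, panel = data.frame(group = "Len",
                                                   param_index = 1:3))
  expect_equal(agg$aggregates$total, 1)
})

test_that("weighted aggregation matches hand-computed means", {
  pat <- data.frame(trajectory = "t", param_index = c(1, 3),
                    param_name = feature_definitions()$param_name[c(1, 3)],
                    unit = "m", value = c(1, 2), flag = "")
  ref <- data.frame(group = "g", trajectory = "t", param_index = c(1, 3),
                    param_name = pat$param_name, mean = c(1, 1), std = 0,
                    unit = "m")
  card <- parameter_scores(pat, ref)  # scores 1.0 and 0.5
  panel <- data.frame(group = "Len", param_index = c(1, 3))
  eq <- aggregate_scores(card, panel)
  expect_equal(eq$aggregates$total, 0.75)
  w <- aggregate_scores(card, panel,
                        param_weights = data.frame(param_index = c(1, 3),
                                                   weight = c(3, 1)))
  expect_equal(w$aggregates$total, 0.875)
  expect_error(aggregate_scores(card, panel,
                                param_weights = data.frame(
                                  param_index = c(1, 3), weight = c(0, 0))),
               "aggregation error")
})

test_that("aggregates are convex and invariant to weight rescaling", {
  card <- self_score_card(aggregate = FALSE)
  set.seed(60)
  card$scores$score_raw <- stats::runif(nrow(card$scores), 0.5, 1.5)
  agg <- aggregate_scores(card)
  # every aggregate lies within the range of its members
  rng <- range(agg$aggregates$sectors$score)
  expect_gte(agg$aggregates$total, rng[1])
  expect_lte(agg$aggregates$total, rng[2])
  for (k in seq_len(nrow(agg$aggregates$per_trajectory))) {
    tr <- agg$aggregates$per_trajectory$trajectory[k]
    member <- card$scores$score_raw[card$scores$trajectory == tr &
                                      card$scores$param_index %in%
                                        default_panel()$param_index]
    expect_gte(agg$aggregates$per_trajectory$score[k], min(member) - 1e-12)
    expect_lte(agg$aggregates$per_trajectory$score[k], max(member) + 1e-12)
  }

  # the weighted means are invariant under rescaling all weights
  panel <- data.frame(group = "Len", param_index = c(1, 3))
  w1 <- aggregate_scores(card, panel,
                         param_weights = data.frame(param_index = c(1, 3),
                                                    weight = c(1, 3)))
  w2 <- aggregate_scores(card, panel,
                         param_weights = data.frame(param_index = c(1, 3),
                                                    weight = c(10, 30)))
  expect_equal(w1$aggregates$total, w2$aggregates$total, tolerance = 1e-12)
  expect_equal(w1$aggregates$per_trajectory$score,
               w2$aggregates$per_trajectory$score, tolerance = 1e-12)
})

test_that("the default star panel has 17 sectors in groups 6/6/5", {
  panel <- default_panel()
  expect_equal(nrow(panel), 17L)
  expect_equal(as.integer(table(panel$group)[c("Ang", "Len", "Vol")]),
               c(6L, 6L, 5L))
  card <- self_score_card()
  star <- star_plot_export(card)
  expect_equal(nrow(star$sectors), 17L)
  expect_equal(nrow(star$groups), 3L)
  expect_true(all(abs(star$sectors$radius - 1) < 1e-12))
  expect_equal(star$total, 1, tolerance = 1e-12)
  # deterministic ordering: groups in Ang, Len, Vol blocks
  expect_equal(rle(star$sectors$group)$values, c("Ang", "Len", "Vol"))
})

test_that("star export writes json and refuses unaggregated cards", {
  card <- self_score_card()
  path <- withr::local_tempfile(fileext = ".json")
  star_plot_export(card, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(nrow(back$sectors), 17L)
  raw <- self_score_card(aggregate = FALSE)
  expect_error(star_plot_export(raw), "not aggregated")
})

test_that("angle scores follow the per-joint weighted formulas", {
  pt <- data.frame(joint = "shoulder", axis = c("x", "y", "z"),
                   value = c(10, 10, 20))
  ref <- data.frame(joint = "shoulder", axis = c("x", "y", "z"),
                    value = c(10, 10, 10))
  eq <- angle_scores(pt, ref)
  expect_equal(eq$joint_scores$score, 5 / 6)
  expect_equal(eq$total, 5 / 6)
  w <- angle_scores(pt, ref,
                    axis_weights = data.frame(joint = "shoulder",
                                              axis = c("x", "y", "z"),
                                              weight = c(0, 0, 1)))
  expect_equal(w$joint_scores$score, 0.5)
  ident <- angle_scores(ref, ref)
  expect_equal(ident$total, 1)
})

test_that("contralateral scoring is antisymmetric under side exchange", {
  tl <- random_traj(40, seed = 70); tl$label <- "wrist_l_in_girdle_l"
  tr_ <- random_traj(40, seed = 71); tr_$label <- "wrist_r_in_girdle_r"
  fl <- features_table(tl)
  fr <- features_table(tr_)
  a <- contralateral_reference(fl, fr)
  b <- contralateral_reference(fr, fl)
  m <- merge(a$scores, b$scores, by = "param_index")
  keep <- is.finite(m$score_raw.x) & is.finite(m$score_raw.y) &
    abs(m$score_raw.y) > 1e-9
  expect_gt(sum(keep), 30)
  expect_lt(max(abs(m$score_raw.x[keep] - 1 / m$score_raw.y[keep]) /
                  pmax(abs(m$score_raw.x[keep]), 1e-9)), 1e-9)

  # symmetric performance scores to 1
  sym <- contralateral_reference(fl, {
    f2 <- fl; f2$trajectory <- mirror_label(f2$trajectory); f2
  })
  expect_true(all(abs(sym$scores$score_raw - 1) < 1e-12, na.rm = TRUE))

  bad <- fr; bad$trajectory <- "elbow_r_in_shoulder_r"
  expect_error(contralateral_reference(fl, bad), "pairing error")
})
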