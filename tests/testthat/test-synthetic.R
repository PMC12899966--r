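test_that("the intensity envelope follows neutral/ramp/hold/release", {
  cfg <- generator_config()
  expect_equal(envelope(0.5, cfg), 0)      # neutral
  expect_equal(envelope(1.5, cfg), 0.5)    # mid-ramp on [1, 2]
  expect_equal(envelope(3, cfg), 1)        # apex hold
  expect_equal(envelope(4.5, cfg), 0.5)    # mid-release on [4, 5]
  expect_equal(envelope(5, cfg), 0)
  expect_error(envelope(5.1, cfg), "outside")
  expect_true(all(envelope(seq(0, 5, by = 0.01), cfg) >= 0))
  expect_true(all(envelope(seq(0, 5, by = 0.01), cfg) <= 1))
})

test_that("clean joy recordings activate only the joy signature", {
  cfg <- generator_config(n_subjects = 1, sigma_obs = 0, baseline_scale = 0,
                          dropout_p = 0, bleed = 0, style_sd = 0, seed = 3)
  set.seed(3)
  subj <- list(subject_id = "s01", fps = 30,
               baseline = rep(0, 52), expressiveness = 1,
               style = setNames(rep(1, 52), arkit_blendshapes()))
  g <- generate_recording("joy", subj, cfg)
  active_cols <- colnames(g$recording$values)[colSums(g$recording$values) > 0]
  expect_setequal(active_cols, relevant_blendshapes("joy"))
  # peak value equals the drawn amplitude (envelope reaches exactly 1)
  for (k in names(g$truth$amplitudes)) {
    expect_equal(max(g$recording$values[, k]),
                 unname(g$truth$amplitudes[k]), tolerance = 1e-12)
  }
})

test_that("contempt activates exactly one unilateral variant", {
  cfg <- generator_config(n_subjects = 1, sigma_obs = 0, baseline_scale = 0,
                          dropout_p = 0, style_sd = 0, seed = 5)
  subj <- list(subject_id = "s01", fps = 30,
               baseline = rep(0, 52), expressiveness = 1,
               style = setNames(rep(1, 52), arkit_blendshapes()))
  sides_seen <- character(0)
  for (i in 1:10) {
    g <- generate_recording("contempt", subj, cfg)
    side <- g$truth$contempt_side
    sides_seen <- c(sides_seen, side)
    off <- if (side == "left") c("mouthDimpleRight", "mouthSmileRight")
           else c("mouthDimpleLeft", "mouthSmileLeft")
    expect_true(all(g$recording$values[, off] == 0))
    on <- if (side == "left") c("mouthDimpleLeft", "mouthSmileLeft")
          else c("mouthDimpleRight", "mouthSmileRight")
    expect_true(all(colSums(g$recording$values[, on]) > 0))
  }
  expect_setequal(unique(sides_seen), c("left", "right"))
})

test_that("all raw generated values lie in [0, 1]", {
  sim <- generate_cohort(generator_config(n_subjects = 3, sigma_obs = 0.4,
                                          seed = 8))
  for (r in sim$cohort$recordings) {
    expect_true(all(r$values >= 0 & r$values <= 1))
    expect_false(r$standardized)
  }
})

test_that("the generator is deterministic under its seed", {
  cfg <- generator_config(n_subjects = 2, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(
    lapply(a$cohort$recordings, `[[`, "values"),
    lapply(b$cohort$recordings, `[[`, "values")
  )
  expect_identical(a$truth$info, b$truth$info)
  c2 <- generate_cohort(generator_config(n_subjects = 2, seed = 78))
  expect_false(identical(a$cohort$recordings[[1]]$values,
                         c2$cohort$recordings[[1]]$values))
})

test_that("protocol counts: 7 emotions per subject, 43 with movements", {
  sim <- generate_cohort(generator_config(n_subjects = 31, seed = 1))
  expect_identical(length(sim$cohort), 217L)
  sim2 <- generate_cohort(generator_config(n_subjects = 2, movements = TRUE,
                                           seed = 1))
  expect_identical(length(sim2$cohort), 86L)
  info <- cohort_info(sim2$cohort)
  expect_true(all(table(info$subject_id) == 43))
  expect_error(generator_config(n_subjects = 0), "n_subjects")
})

test_that("sustained-phase means recover drawn amplitudes in closed form", {
  cfg <- generator_config(n_subjects = 1, sigma_obs = 0, baseline_scale = 0,
                          dropout_p = 0, bleed = 0, style_sd = 0,
                          expressiveness_sd = 0, seed = 4)
  sim <- generate_cohort(cfg)
  rec <- sim$cohort$recordings[["s01_joy"]]
  sus <- select_sustained_phase(rec, 1.0)
  env_mean <- mean(envelope(sus$t, cfg))
  amps <- sim$truth$amplitudes[["s01_joy"]]
  for (k in names(amps)) {
    expect_equal(mean(sus$values[, k]), unname(amps[k]) * env_mean,
                 tolerance = 1e-12)
  }
})

test_that("FPS mixture approaches the configured weight", {
  cfg <- generator_config(n_subjects = 200, seed = 13)
  set.seed(cfg$seed)
  fps <- vapply(arkemo:::.draw_subject_params(cfg), `[[`, numeric(1), "fps")
  p_hat <- mean(fps == 60)
  se <- sqrt(0.8067 * (1 - 0.8067) / 200)
  expect_lt(abs(p_hat - 0.8067), 4 * se)
})

test_that("synthetic raters follow the confusability matrix", {
  sim <- generate_cohort(generator_config(n_subjects = 10, seed = 21))
  # identity confusability: all raters agree perfectly
  r_id <- generate_rater_labels(sim$truth, diag(7), n_raters = 3, seed = 1)
  expect_equal(krippendorff_alpha(r_id), 1.0)
  # uniform confusability: chance-level agreement
  unif <- matrix(1 / 7, 7, 7)
  r_unif <- generate_rater_labels(sim$truth, unif, n_raters = 3, seed = 1)
  expect_lt(abs(krippendorff_alpha(r_unif)), 0.15)
  # fear <-> surprise confusable raters put fear's largest off-diagonal
  # rater-confusion mass on surprise
  conf <- diag(7) * 0.6 + 0.4 / 7
  fi <- match("fear", emotions()); si <- match("surprise", emotions())
  conf[fi, ] <- 0; conf[fi, fi] <- 0.5; conf[fi, si] <- 0.5
  conf <- conf / rowSums(conf)
  r_fs <- generate_rater_labels(sim$truth, conf, n_raters = 5, seed = 2)
  truth_by_id <- setNames(sim$truth$info$label, sim$truth$info$recording_id)
  fear_rows <- r_fs[truth_by_id[r_fs$recording_id] == "fear", ]
  tab <- table(factor(fear_rows$label, levels = emotions()))
  off <- tab[names(tab) != "fear"]
  expect_identical(names(which.max(off)), "surprise")
  expect_error(generate_rater_labels(sim$truth, matrix(1, 7, 7)),
               "stochastic")
})
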