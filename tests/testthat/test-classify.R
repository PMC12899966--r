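test_that("cosine similarity matches hand-evaluated values", {
  v <- c(1, 2, 3, rep(0, 49))
  p <- c(4, 5, 6, rep(0, 49))
  expect_equal(cosine_similarity(v, p), 0.9746318, tolerance = 1e-6)
  expect_equal(cosine_similarity(v, v), 1.0)
  e1 <- c(1, rep(0, 51)); e2 <- c(0, 1, rep(0, 50))
  expect_equal(cosine_similarity(e1, e2), 0)
  # scale invariance
  expect_equal(cosine_similarity(3.7 * v, p), cosine_similarity(v, p))
  # zero-vector fallback
  expect_equal(cosine_similarity(rep(0, 52), p), 0)
})

test_that("cosine similarity matches the brute-force oracle", {
  set.seed(301)
  for (i in 1:200) {
    v <- rnorm(52); p <- rnorm(52)
    expect_equal(cosine_similarity(v, p), oracle_cosine(v, p),
                 tolerance = 1e-12)
  }
})

test_that("prototypes are frame means per emotion", {
  # two joy frames e1 and e2 -> prototype (0.5, 0.5, 0, ...)
  reg <- arkit_blendshapes()
  mk <- function(rows, label, subject) {
    bs_recording(rows, t = (seq_len(nrow(rows)) - 1) / 30, subject, label,
                 30, standardized = TRUE)
  }
  recs <- list()
  for (e in emotions()) {
    rows <- matrix(0, 2, 52, dimnames = list(NULL, reg))
    if (e == "joy") {
      rows[1, 1] <- 1; rows[2, 2] <- 1
    } else {
      rows[, match(e, emotions()) + 2] <- 1
    }
    recs[[e]] <- mk(rows, e, "s01")
  }
  ps <- fit_prototypes(bs_cohort(recs), mode = "in_sample")
  expect_equal(unname(ps$prototypes["joy", 1:3]), c(0.5, 0.5, 0))
  # single recording per emotion: prototype equals that recording's mean
  expect_equal(ps$prototypes["fear", ],
               colMeans(recs$fear$values), tolerance = 1e-12)
})

test_that("LOSO prototypes exclude the held-out subject's frames", {
  set.seed(302)
  co <- random_cohort(n_subjects = 3, n = 5, standardized = TRUE)
  ps <- fit_prototypes(co, mode = "leave_one_subject_out")
  expect_identical(ps$fit_mode, "leave_one_subject_out")
  # brute-force refit without s02
  rest <- Filter(function(r) r$subject_id != "s02", co$recordings)
  for (e in emotions()) {
    x <- do.call(rbind, lapply(
      Filter(function(r) r$label == e, rest), `[[`, "values"))
    expect_equal(ps$by_subject$s02[e, ], colMeans(x), tolerance = 1e-12)
  }
  expect_error(fit_prototypes(bs_cohort(co$recordings[1:6])),
               "no recordings for emotion")
})

test_that("frame classification equals an exhaustive similarity scan", {
  set.seed(303)
  co <- random_cohort(n_subjects = 2, n = 5, standardized = TRUE)
  ps <- fit_prototypes(co, mode = "in_sample")
  for (i in 1:300) {
    v <- rnorm(52)
    got <- classify_frame(v, ps)
    sims <- vapply(emotions(), function(e)
      oracle_cosine(v, ps$prototypes[e, ]), numeric(1))
    expect_equal(unname(got$scores), unname(sims), tolerance = 1e-12)
    expect_identical(got$emotion, emotions()[which.max(sims)])
  }
})

test_that("a frame equal to a prototype is classified as that emotion", {
  set.seed(304)
  co <- random_cohort(n_subjects = 2, n = 5, standardized = TRUE)
  ps <- fit_prototypes(co, mode = "in_sample")
  got <- classify_frame(ps$prototypes["fear", ], ps)
  expect_identical(got$emotion, "fear")
  expect_equal(unname(got$scores["fear"]), 1.0, tolerance = 1e-12)
  # all-zero frame: all scores 0, canonical tie-break, flagged ambiguous
  got0 <- classify_frame(rep(0, 52), ps)
  expect_identical(got0$emotion, "anger")
  expect_true(got0$ambiguous)
  expect_true(all(got0$scores == 0))
})

test_that("negated prototype frames are pushed away from their emotion", {
  reg <- arkit_blendshapes()
  # orthogonal one-hot prototypes
  protos <- matrix(0, 7, 52, dimnames = list(emotions(), reg))
  for (i in 1:7) protos[i, i] <- 1
  ps <- structure(list(prototypes = protos, fit_mode = "in_sample"),
                  class = "prototype_set")
  v <- -protos["joy", ]
  got <- classify_frame(v, ps)
  expect_equal(unname(got$scores["joy"]), -1)
  expect_false(got$emotion == "joy")
})

test_that("recording aggregation: mean score and frame vote", {
  reg <- arkit_blendshapes()
  # all frames identical: both aggregations agree with classify_frame
  set.seed(305)
  co <- random_cohort(n_subjects = 2, n = 4, standardized = TRUE)
  ps <- fit_prototypes(co, mode = "in_sample")
  v <- rnorm(52)
  rows <- matrix(rep(v, 3), nrow = 3, byrow = TRUE,
                 dimnames = list(NULL, reg))
  rec <- bs_recording(rows, t = 0:2 / 30, "s01", "joy", 30,
                      standardized = TRUE)
  pm <- classify_recording(rec, ps, aggregation = "mean_score")
  pv <- classify_recording(rec, ps, aggregation = "frame_vote")
  pf <- classify_frame(v, ps)
  expect_identical(pm$predicted, pf$emotion)
  expect_identical(pv$predicted, pf$emotion)
  # mean_score arithmetic: joy (0.9 + 0.9 + 0.1) / 3 beats sadness mean 0.4
  fs <- matrix(0, 3, 7, dimnames = list(NULL, emotions()))
  fs[, "joy"] <- c(0.9, 0.9, 0.1)
  fs[, "sadness"] <- c(0.2, 0.2, 0.8)
  ms <- colMeans(fs)
  expect_identical(names(which.max(ms)), "joy")
  expect_equal(unname(ms["joy"]), 0.6333333, tolerance = 1e-6)
  # frame_vote majority: labels joy, joy, sadness -> joy
  votes <- apply(fs, 1, function(r) names(which.max(r)))
  expect_identical(names(which.max(table(votes))), "joy")
})

test_that("cosine predictions are invariant to positive rescaling", {
  set.seed(306)
  sim <- generate_cohort(generator_config(n_subjects = 3, seed = 7))
  prep <- preprocess_cohort(sim$cohort)
  ps <- fit_prototypes(prep$cohort)
  for (a in c(0.2, 5)) {
    scaled <- cohort_map(prep$cohort, function(r) {
      bs_recording(a * r$values, r$t, r$subject_id, r$label, r$fps,
                   standardized = TRUE, id = r$id)
    })
    p1 <- classify_cohort(prep$cohort, ps)
    p2 <- classify_cohort(scaled, ps)
    expect_identical(p2$predicted, p1$predicted)
    expect_equal(p2[paste0("score_", emotions())],
                 p1[paste0("score_", emotions())], tolerance = 1e-12)
  }
})

test_that("emotion label permutation permutes predictions accordingly", {
  set.seed(307)
  co <- random_cohort(n_subjects = 2, n = 5, standardized = TRUE)
  perm <- setNames(sample(emotions()), emotions())
  co_perm <- cohort_map(co, function(r) {
    bs_recording(r$values, r$t, r$subject_id, perm[[r$label]], r$fps,
                 standardized = TRUE,
                 id = paste(r$subject_id, perm[[r$label]], sep = "_"))
  })
  ps <- fit_prototypes(co, mode = "in_sample")
  ps_perm <- fit_prototypes(co_perm, mode = "in_sample")
  p1 <- classify_cohort(co, ps)
  p2 <- classify_cohort(co_perm, ps_perm)
  # same recording (by subject + original label) must map to permuted label
  key1 <- paste(p1$subject_id, perm[p1$truth])
  key2 <- paste(p2$subject_id, p2$truth)
  expect_identical(unname(perm[p1$predicted[match(key2, key1)]]),
                   p2$predicted)
})

test_that("baseline scores are means over EMFACS-relevant shapes", {
  reg <- arkit_blendshapes()
  rows <- matrix(0, 2, 52, dimnames = list(NULL, reg))
  rows[, c("mouthSmileLeft", "mouthSmileRight")] <- 0.9
  rows[, c("cheekSquintLeft", "cheekSquintRight")] <- 0.8
  rec <- bs_recording(rows, t = 0:1 / 30, "s01", "joy", 30)
  pred <- baseline_classify_recording(rec)
  expect_identical(pred$predicted, "joy")
  expect_equal(unname(pred$scores["joy"]), 0.85)
  # every other emotion's mean is below joy's
  expect_true(all(pred$scores[names(pred$scores) != "joy"] < 0.85))
  # all-zero recording: 7-way tie, canonical order, flagged
  rec0 <- bs_recording(matrix(0, 2, 52, dimnames = list(NULL, reg)),
                       t = 0:1 / 30, "s01", "joy", 30)
  p0 <- baseline_classify_recording(rec0)
  expect_identical(p0$predicted, "anger")
  expect_true(p0$ambiguous)
  # unilateral left contempt wins via the variant maximum
  rows2 <- matrix(0, 2, 52, dimnames = list(NULL, reg))
  rows2[, c("mouthDimpleLeft", "mouthSmileLeft")] <- 0.8
  rec2 <- bs_recording(rows2, t = 0:1 / 30, "s01", "contempt", 30)
  p2 <- baseline_classify_recording(rec2)
  expect_identical(p2$predicted, "contempt")
  expect_equal(unname(p2$scores["contempt"]), 0.8)
})

test_that("prototype CSV save/load round-trips", {
  set.seed(308)
  co <- random_cohort(n_subjects = 2, n = 4, standardized = TRUE)
  ps <- fit_prototypes(co, mode = "in_sample")
  path <- withr::local_tempfile(fileext = ".csv")
  write_prototypes(ps, path)
  back <- read_prototypes(path)
  expect_identical(back$prototypes, ps$prototypes)
})
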