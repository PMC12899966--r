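# Default apex amplitude per blend shape. Qualitative, desk-scale stand-ins
# for the activation ranges a TrueDepth capture shows: near-saturating shapes
# (cheek puff, blinks, tongue, upward gaze, lateral mouth) sit near 1,
# narrow-range shapes (lateral/forward jaw, downward gaze, dimples,
# stretches) sit near 0.5, everything else at 0.8.
.default_apex_amplitudes <- function() {
  amp <- stats::setNames(rep(0.8, 52), arkit_blendshapes())
  amp[c("eyeLookUpLeft", "eyeLookUpRight")] <- 1.0
  amp[c("cheekPuff", "eyeBlinkLeft", "eyeBlinkRight", "tongueOut",
        "mouthLeft", "mouthRight")] <- 0.95
  amp[c("eyeLookDownLeft", "eyeLookDownRight", "mouthDimpleLeft",
        "mouthDimpleRight", "mouthStretchLeft", "mouthStretchRight",
        "jawForward", "jawRight")] <- 0.55
  amp["jawLeft"] <- 0.45
  amp
}

# Blend shapes shared between the fear and surprise EMFACS signatures: the
# surprise signature is a strict subset of fear's, and this overlap drives
# the fear -> surprise confusion the classifier shows on real faces.
.fear_surprise_shared <- function(emfacs = emfacs_table()) {
  intersect(names(emfacs$mapping$fear), names(emfacs$mapping$surprise))
}

#' Synthetic cohort generator configuration
#'
#' Parameters of the posed-expression protocol the generator emulates: each
#' recording lasts `duration_s` seconds and runs neutral (to `neutral_end`),
#' linear ramp to apex (to `apex_start`), apex hold (to `apex_end`), then
#' linear release to the end. Emotion recordings activate the EMFACS
#' signature blend shapes of their emotion; movement recordings drive one
#' blend shape (or symmetric pair). Subjects differ in a resting baseline
#' offset and a multiplicative expressiveness scale; observation noise is
#' additive Gaussian; all raw values are clipped to \[0, 1\].
#'
#' @param n_subjects Number of subjects (default 31).
#' @param duration_s Recording length in seconds (default 5).
#' @param neutral_end,apex_start,apex_end Envelope timings in seconds
#'   (defaults 1, 2, 4).
#' @param p60 Probability that a subject records at 60 FPS rather than 30
#'   (default 0.8067, the mixture observed under the protocol).
#' @param apex_amplitudes Named length-52 vector of per-blend-shape apex
#'   amplitudes in (0, 1\].
#' @param amplitude_jitter Per-recording multiplicative jitter: each active
#'   shape's amplitude is scaled by `U(1 - amplitude_jitter, 1)`
#'   (default 0.25).
#' @param baseline_scale Upper bound of the per-subject, per-shape resting
#'   activation offset, drawn `U(0, baseline_scale)` (default 0.04).
#' @param expressiveness_sd Log-sd of the per-subject expressiveness scale,
#'   drawn log-normal with median 1 (default 0.2). Set 0 to disable.
#' @param style_sd Log-sd of the per-subject, per-blend-shape expression
#'   style weight, drawn log-normal with median 1 once per subject and
#'   applied to every activation of that shape (default 0.5). This is the
#'   dominant realistic difficulty: subjects emphasize different components
#'   of the same expression, so prototypes fit on other subjects transfer
#'   imperfectly. Set 0 to disable.
#' @param sigma_obs Additive Gaussian observation noise sd (default 0.05).
#' @param dropout_p Probability that each signature blend shape of an
#'   emotion recording fails to be produced at all in that recording
#'   (default 0.25; at least one shape always survives). Posed expressions
#'   are routinely incomplete — a subject's fear may lack the mouth stretch,
#'   say — and this incompleteness, not sensor noise, is what drives
#'   confusions between emotions with overlapping signatures. Movement
#'   recordings are directly coached and are not subject to dropout.
#' @param bleed Fear/surprise cross-signature bleed in \[0, 1\]: amplitudes
#'   of fear-specific shapes (those not shared with surprise) are scaled by
#'   `1 - bleed` in fear recordings, pushing fear toward surprise's
#'   direction (default 0.25; set 0 to disable).
#' @param contempt_p_left Probability that a contempt recording activates
#'   the left-side variant (default 0.5).
#' @param exclusivity Enforce opposite-pair mutual exclusivity: per frame,
#'   when both members of an opposite pair are positive the smaller is
#'   forced to 0 (default `TRUE`).
#' @param squint_wide_exception Exempt the eyeWide/eyeSquint pairs from the
#'   exclusivity rule — these are near- rather than strictly opposite and do
#'   co-activate (default `TRUE`).
#' @param movements Also generate the 36 single-movement recordings per
#'   subject (default `FALSE`).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including the seed.
#' @return A `generator_config` list (validated).
#' @export
generator_config <- function(n_subjects = 31, duration_s = 5,
                             neutral_end = 1, apex_start = 2, apex_end = 4,
                             p60 = 0.8067,
                             apex_amplitudes = .default_apex_amplitudes(),
                             amplitude_jitter = 0.25,
                             baseline_scale = 0.04,
                             expressiveness_sd = 0.2,
                             style_sd = 0.5,
                             sigma_obs = 0.05,
                             dropout_p = 0.25,
                             bleed = 0.25,
                             contempt_p_left = 0.5,
                             exclusivity = TRUE,
                             squint_wide_exception = TRUE,
                             movements = FALSE,
                             seed = 1) {
  cfg <- list(
    n_subjects = n_subjects, duration_s = duration_s,
    neutral_end = neutral_end, apex_start = apex_start, apex_end = apex_end,
    p60 = p60, apex_amplitudes = apex_amplitudes,
    amplitude_jitter = amplitude_jitter, baseline_scale = baseline_scale,
    expressiveness_sd = expressiveness_sd, style_sd = style_sd,
    sigma_obs = sigma_obs,
    dropout_p = dropout_p, bleed = bleed,
    contempt_p_left = contempt_p_left,
    exclusivity = exclusivity,
    squint_wide_exception = squint_wide_exception,
    movements = movements, seed = seed
  )
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (!(0 <= neutral_end && neutral_end < apex_start &&
        apex_start <= apex_end && apex_end <= duration_s)) {
    stop("envelope timings must satisfy 0 <= neutral_end < apex_start <= ",
         "apex_end <= duration_s", call. = FALSE)
  }
  if (!identical(sort(names(apex_amplitudes)), sort(arkit_blendshapes()))) {
    stop("apex_amplitudes must name all 52 blend shapes", call. = FALSE)
  }
  if (any(apex_amplitudes <= 0) || any(apex_amplitudes > 1)) {
    stop("apex amplitudes must lie in (0, 1]", call. = FALSE)
  }
  if (sigma_obs < 0) stop("sigma_obs must be >= 0", call. = FALSE)
  if (dropout_p < 0 || dropout_p >= 1) {
    stop("dropout_p must be in [0, 1)", call. = FALSE)
  }
  if (bleed < 0 || bleed > 1) stop("bleed must be in [0, 1]", call. = FALSE)
  if (amplitude_jitter < 0 || amplitude_jitter >= 1) {
    stop("amplitude_jitter must be in [0, 1)", call. = FALSE)
  }
  if (p60 < 0 || p60 > 1) stop("p60 must be in [0, 1]", call. = FALSE)
  structure(cfg, class = "generator_config")
}

#' Expression intensity envelope
#'
#' The time course every synthetic recording follows: 0 during the neutral
#' phase, a linear ramp to apex, an apex hold at 1, and a linear release to
#' 0 at the end of the recording.
#'
#' @param t Time(s) in seconds, within `[0, duration_s]`.
#' @param config A [generator_config()] (only the timing fields are used).
#' @return Numeric vector of intensities in \[0, 1\].
#' @export
#' @examples
#' envelope(c(0.5, 1.5, 3, 4.5), generator_config())
envelope <- function(t, config = generator_config()) {
  if (any(t < 0 | t > config$duration_s)) {
    stop("t outside recording [0, ", config$duration_s, "]", call. = FALSE)
  }
  ne <- config$neutral_end; as_ <- config$apex_start
  ae <- config$apex_end; d <- config$duration_s
  ifelse(t < ne, 0,
    ifelse(t < as_, (t - ne) / (as_ - ne),
      ifelse(t < ae, 1,
        if (d > ae) (d - t) / (d - ae) else 1)))
}

# Zero the smaller member of each opposite pair wherever both are positive
# (ties zero the second member), optionally exempting eyeWide/eyeSquint.
.apply_exclusivity <- function(values, config) {
  pairs <- opposite_pairs()
  if (config$squint_wide_exception) {
    keep <- !(pairs$blendshape_1 %in% c("eyeWideLeft", "eyeWideRight"))
    pairs <- pairs[keep, ]
  }
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$blendshape_1[i]; b <- pairs$blendshape_2[i]
    both <- values[, a] > 0 & values[, b] > 0
    if (!any(both)) next
    a_wins <- values[both, a] >= values[both, b]
    values[both, a][!a_wins] <- 0
    values[both, b][a_wins] <- 0
  }
  values
}

# Per-subject latent parameters drawn once per cohort.
.draw_subject_params <- function(config) {
  lapply(seq_len(config$n_subjects), function(i) {
    list(
      subject_id = sprintf("s%02d", i),
      fps = if (stats::runif(1) < config$p60) 60 else 30,
      baseline = stats::runif(52, 0, config$baseline_scale),
      expressiveness = if (config$expressiveness_sd > 0) {
        stats::rlnorm(1, 0, config$expressiveness_sd)
      } else 1,
      style = stats::setNames(
        if (config$style_sd > 0) {
          stats::rlnorm(52, 0, config$style_sd)
        } else rep(1, 52),
        arkit_blendshapes())
    )
  })
}

#' Generate one synthetic expression recording
#'
#' Draws one recording for a given label and subject: per-shape amplitudes
#' are the configured apex amplitudes with multiplicative jitter, scaled by
#' the subject's expressiveness and the intensity envelope, offset by the
#' subject's resting baseline, perturbed by observation noise, clipped to
#' \[0, 1\], and subjected to opposite-pair exclusivity. Contempt activates
#' one unilateral variant only; fear recordings attenuate fear-specific
#' shapes by the configured bleed. Draws from the current RNG stream (seed
#' at the cohort level for reproducibility).
#'
#' @param label One of the 7 emotions or 36 movement names.
#' @param subject List with `subject_id`, `fps`, `baseline` (length-52),
#'   `expressiveness` (as produced internally by [generate_cohort()]).
#' @param config A [generator_config()].
#' @param emfacs An [emfacs_table()].
#' @return List with `recording` (a raw [bs_recording()]) and `truth`
#'   (list: `recording_id`, `label`, `contempt_side` or `NA`, `amplitudes`
#'   named vector of the drawn apex amplitudes).
#' @export
generate_recording <- function(label, subject, config = generator_config(),
                               emfacs = emfacs_table()) {
  reg <- arkit_blendshapes()
  contempt_side <- NA_character_
  if (label %in% emotions()) {
    if (label == "contempt") {
      contempt_side <- if (stats::runif(1) < config$contempt_p_left) "left"
                       else "right"
      active <- emfacs$contempt_variants[[contempt_side]]
    } else {
      active <- names(emfacs$mapping[[label]])
    }
  } else {
    active <- movement_blendshapes(label)
  }
  if (label %in% emotions() && config$dropout_p > 0) {
    produced <- stats::runif(length(active)) >= config$dropout_p
    if (!any(produced)) produced[sample(length(active), 1)] <- TRUE
    active <- active[produced]
  }
  n <- as.integer(round(config$duration_s * subject$fps))
  t <- (seq_len(n) - 1) / subject$fps
  env <- envelope(t, config)
  amp <- config$apex_amplitudes[active] * subject$style[active] *
    stats::runif(length(active), 1 - config$amplitude_jitter, 1)
  if (label == "fear" && config$bleed > 0) {
    fear_only <- setdiff(active, .fear_surprise_shared(emfacs))
    amp[fear_only] <- amp[fear_only] * (1 - config$bleed)
  }
  values <- matrix(0, n, 52, dimnames = list(NULL, reg))
  values[, active] <- outer(env, subject$expressiveness * amp)
  values <- sweep(values, 2, subject$baseline, "+")
  if (config$sigma_obs > 0) {
    values <- values + matrix(stats::rnorm(n * 52, 0, config$sigma_obs),
                              n, 52)
  }
  values <- pmin(pmax(values, 0), 1)
  if (config$exclusivity) values <- .apply_exclusivity(values, config)
  rec <- bs_recording(values, t = t, subject_id = subject$subject_id,
                      label = label, fps = subject$fps)
  list(
    recording = rec,
    truth = list(recording_id = rec$id, label = label,
                 contempt_side = contempt_side,
                 amplitudes = stats::setNames(as.numeric(amp), active))
  )
}

#' Generate a synthetic cohort
#'
#' Emits, per subject, one recording of each of the 7 emotions (and, when
#' `config$movements` is `TRUE`, the 36 movement recordings), following the
#' recording protocol encoded in the configuration. Fully deterministic
#' given the configuration (including its seed).
#'
#' @param config A [generator_config()].
#' @return List with `cohort` (a raw [bs_cohort()]) and `truth` (list:
#'   `info` data frame with one row per recording — `recording_id`,
#'   `subject_id`, `label`, `fps`, `contempt_side` — and `amplitudes`, a
#'   list of drawn amplitude vectors keyed by recording id).
#' @export
#' @examples
#' out <- generate_cohort(generator_config(n_subjects = 2, seed = 7))
#' out$cohort
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  subjects <- .draw_subject_params(config)
  labels <- c(emotions(), if (config$movements) movement_labels())
  emf <- emfacs_table()
  recs <- list()
  rows <- list()
  amps <- list()
  for (s in subjects) {
    for (lab in labels) {
      g <- generate_recording(lab, s, config, emf)
      recs[[g$recording$id]] <- g$recording
      rows[[g$recording$id]] <- data.frame(
        recording_id = g$recording$id, subject_id = s$subject_id,
        label = lab, fps = s$fps, contempt_side = g$truth$contempt_side
      )
      amps[[g$recording$id]] <- g$truth$amplitudes
    }
  }
  list(
    cohort = bs_cohort(recs),
    truth = list(info = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 amplitudes = amps)
  )
}

#' Generate synthetic human-rater labels
#'
#' Emulates independent raters labelling each emotion recording: each rater
#' draws a label from the row of a confusability matrix corresponding to the
#' recording's true emotion. An identity matrix gives perfect agreement; a
#' uniform matrix gives chance-level agreement (alpha near 0).
#'
#' @param truth Truth object from [generate_cohort()] (or any data frame
#'   with `recording_id` and `label` columns restricted to emotions).
#' @param confusability 7 x 7 row-stochastic matrix (rows/cols in canonical
#'   emotion order): `confusability[i, j]` is the probability a rater labels
#'   a true-emotion-i recording as emotion j.
#' @param n_raters Number of raters (default 3).
#' @param seed Integer seed.
#' @return Data frame with columns `rater_id`, `recording_id`, `label`.
#' @export
generate_rater_labels <- function(truth, confusability = diag(7),
                                  n_raters = 3, seed = 1) {
  info <- if (is.data.frame(truth)) truth else truth$info
  info <- info[info$label %in% emotions(), ]
  confusability <- as.matrix(confusability)
  if (!all(dim(confusability) == c(7, 7)) ||
      any(confusability < 0) ||
      any(abs(rowSums(confusability) - 1) > 1e-8)) {
    stop("confusability must be a 7 x 7 row-stochastic matrix",
         call. = FALSE)
  }
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_raters), function(r) {
    labs <- vapply(info$label, function(e) {
      sample(emotions(), 1, prob = confusability[match(e, emotions()), ])
    }, character(1))
    data.frame(rater_id = sprintf("r%d", r),
               recording_id = info$recording_id,
               label = labs, row.names = NULL)
  }))
  out
}
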