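#' Harmonize a recording to 30 FPS
#'
#' Recordings captured at 60 FPS are downsampled to 30 FPS by dropping every
#' second frame (keeping frames 1, 3, 5, ... in R's 1-based indexing, i.e.
#' even 0-based indices starting at the first frame); 30 FPS recordings pass
#' through unchanged. No interpolation is performed. Idempotent.
#'
#' @param rec A [bs_recording()].
#' @return A 30 FPS [bs_recording()].
#' @export
harmonize_fps <- function(rec) {
  stopifnot(inherits(rec, "bs_recording"))
  if (rec$fps == 30) return(rec)
  if (rec$fps != 60) stop("unsupported fps: ", rec$fps, call. = FALSE)
  keep <- seq(1L, n_frames(rec), by = 2L)
  bs_recording(rec$values[keep, , drop = FALSE], t = rec$t[keep],
               subject_id = rec$subject_id, label = rec$label, fps = 30,
               standardized = rec$standardized, id = rec$id)
}

#' Fit per-subject blend shape statistics
#'
#' Computes, for every subject in the cohort and every blend shape, the mean
#' and standard deviation over all frames of all that subject's recordings.
#' These are the statistics used for subject-wise z-scoring: standardization
#' removes each subject's resting activation level and expressiveness scale.
#'
#' @param cohort A [bs_cohort()] (the fitting set; typically already FPS
#'   harmonized).
#' @param ddof Degrees-of-freedom correction for the standard deviation:
#'   0 (population, default) or 1 (sample).
#' @param scope `"subject"` (default) pools all of a subject's recordings;
#'   `"recording"` fits statistics per recording (sensitivity analysis mode,
#'   keyed by recording id instead of subject id).
#' @return An object of class `subject_stats`: list keyed by subject (or
#'   recording) id, each entry holding `mean` and `sd` vectors of length 52,
#'   plus attributes `ddof` and `scope`.
#' @export
fit_subject_stats <- function(cohort, ddof = 0,
                              scope = c("subject", "recording")) {
  scope <- match.arg(scope)
  stopifnot(inherits(cohort, "bs_cohort"), ddof %in% c(0, 1))
  key <- switch(scope,
    subject = vapply(cohort$recordings, `[[`, character(1), "subject_id"),
    recording = vapply(cohort$recordings, `[[`, character(1), "id")
  )
  stats <- lapply(split(cohort$recordings, key), function(recs) {
    x <- do.call(rbind, lapply(recs, `[[`, "values"))
    n <- nrow(x)
    if (n < 2L) {
      stop("subject with fewer than 2 frames in fitting set", call. = FALSE)
    }
    mu <- colMeans(x)
    ss <- colSums(x^2) - n * mu^2
    ss[ss < 0] <- 0  # guard tiny negative rounding
    list(mean = mu, sd = sqrt(ss / (n - ddof)))
  })
  structure(stats, ddof = ddof, scope = scope, class = "subject_stats")
}

#' Z-score a recording against subject statistics
#'
#' Standardizes each coefficient as `z = (x - mean) / sd` using that
#' subject's statistics from [fit_subject_stats()]. Blend shapes with zero
#' standard deviation (never moving for that subject) are mapped to 0: they
#' carry no directional signal and contribute nothing to cosine similarity.
#'
#' @param rec A raw [bs_recording()].
#' @param stats A `subject_stats` object covering the recording's subject.
#' @return A standardized [bs_recording()].
#' @export
zscore_recording <- function(rec, stats) {
  stopifnot(inherits(rec, "bs_recording"), inherits(stats, "subject_stats"))
  key <- if (identical(attr(stats, "scope"), "recording")) rec$id
         else rec$subject_id
  st <- stats[[key]]
  if (is.null(st)) {
    stop("no statistics for subject ", key, call. = FALSE)
  }
  sd <- st$sd
  sd_safe <- ifelse(sd > 0, sd, 1)
  z <- sweep(rec$values, 2, st$mean, "-")
  z <- sweep(z, 2, sd_safe, "/")
  z[, sd == 0] <- 0
  bs_recording(z, t = rec$t, subject_id = rec$subject_id, label = rec$label,
               fps = rec$fps, standardized = TRUE, id = rec$id)
}

#' Restrict a recording to the sustained expression phase
#'
#' Drops the initial neutral segment: all frames with `t < neutral_cut_s`
#' are removed, keeping the ramp to apex, the apex hold, and the release.
#'
#' @param rec A [bs_recording()].
#' @param neutral_cut_s Length of the neutral segment in seconds (default 1).
#' @return A [bs_recording()] containing only frames with
#'   `t >= neutral_cut_s`.
#' @export
select_sustained_phase <- function(rec, neutral_cut_s = 1.0) {
  stopifnot(inherits(rec, "bs_recording"), neutral_cut_s >= 0)
  if (neutral_cut_s == 0) return(rec)
  if (max(rec$t) < neutral_cut_s) {
    stop("recording shorter than neutral cut (", neutral_cut_s, " s)",
         call. = FALSE)
  }
  keep <- rec$t >= neutral_cut_s
  bs_recording(rec$values[keep, , drop = FALSE], t = rec$t[keep],
               subject_id = rec$subject_id, label = rec$label, fps = rec$fps,
               standardized = rec$standardized, id = rec$id)
}

#' Run the full preprocessing chain on a cohort
#'
#' Applies, in order: FPS harmonization (60 -> 30 by frame dropping),
#' subject-wise z-scoring with statistics fit on all harmonized frames, and
#' sustained-phase selection. This is the preparation step ahead of
#' prototype fitting and classification.
#'
#' @param cohort A raw [bs_cohort()].
#' @param neutral_cut_s Neutral segment length in seconds (default 1).
#' @param ddof,stats_scope Passed to [fit_subject_stats()].
#' @return A list with elements `cohort` (standardized, sustained-phase
#'   [bs_cohort()]), `stats` (the fitted `subject_stats`), and `log` (frame
#'   counts before/after each stage).
#' @export
preprocess_cohort <- function(cohort, neutral_cut_s = 1.0, ddof = 0,
                              stats_scope = "subject") {
  n0 <- sum(vapply(cohort$recordings, n_frames, integer(1)))
  harmonized <- cohort_map(cohort, harmonize_fps)
  n1 <- sum(vapply(harmonized$recordings, n_frames, integer(1)))
  stats <- fit_subject_stats(harmonized, ddof = ddof, scope = stats_scope)
  standardized <- cohort_map(harmonized, zscore_recording, stats = stats)
  sustained <- cohort_map(standardized, select_sustained_phase,
                          neutral_cut_s = neutral_cut_s)
  n2 <- sum(vapply(sustained$recordings, n_frames, integer(1)))
  list(
    cohort = sustained,
    stats = stats,
    log = data.frame(
      stage = c("input", "harmonize_fps", "zscore", "sustained_phase"),
      frames = c(n0, n1, n1, n2)
    )
  )
}
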