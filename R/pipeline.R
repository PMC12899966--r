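#' Run the full emotion-recognition pipeline on a cohort
#'
#' The end-to-end analysis flow: FPS harmonization, subject-wise z-scoring,
#' sustained-phase selection, prototype fitting, classification, and
#' evaluation. The baseline method runs on the same standardized frames by
#' default; set `baseline_raw = TRUE` for the scale-sensitive raw-value
#' variant.
#'
#' @param cohort A raw [bs_cohort()] of emotion recordings (non-emotion
#'   recordings are ignored at classification time).
#' @param method `"cosine"` (prototype similarity) or `"baseline"`
#'   (mean activation of EMFACS-relevant blend shapes).
#' @param fit_mode Prototype fit, `"leave_one_subject_out"` (default) or
#'   `"in_sample"`; ignored for the baseline.
#' @param aggregation Recording-level aggregation for the cosine method,
#'   `"mean_score"` (default) or `"frame_vote"`.
#' @param neutral_cut_s Neutral-phase cut in seconds (default 1).
#' @param emfacs An [emfacs_table()].
#' @param baseline_raw Run the baseline on raw rather than standardized
#'   frames (default `FALSE`).
#' @param raters Optional rater table for agreement metrics.
#' @return List with `report` (an `evaluation_report`), `predictions` (the
#'   [classify_cohort()] data frame), `prototypes` (for the cosine method),
#'   and `log` (preprocessing frame counts).
#' @export
run_pipeline <- function(cohort, method = c("cosine", "baseline"),
                         fit_mode = "leave_one_subject_out",
                         aggregation = "mean_score",
                         neutral_cut_s = 1.0,
                         emfacs = emfacs_table(),
                         baseline_raw = FALSE,
                         raters = NULL) {
  method <- match.arg(method)
  prep <- preprocess_cohort(cohort, neutral_cut_s = neutral_cut_s)
  prototypes <- NULL
  if (method == "cosine") {
    prototypes <- fit_prototypes(prep$cohort, mode = fit_mode)
    preds <- classify_cohort(prep$cohort, prototypes, method = "cosine",
                             aggregation = aggregation)
  } else {
    target <- if (baseline_raw) {
      harmonized <- cohort_map(cohort, harmonize_fps)
      cohort_map(harmonized, select_sustained_phase,
                 neutral_cut_s = neutral_cut_s)
    } else {
      prep$cohort
    }
    preds <- classify_cohort(target, method = "baseline", emfacs = emfacs)
  }
  raters <- if (is.null(raters)) cohort$raters else raters
  list(
    report = evaluate_predictions(preds, raters = raters),
    predictions = preds,
    prototypes = prototypes,
    log = prep$log
  )
}
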