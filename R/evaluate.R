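#' Overall and per-emotion classification accuracy
#'
#' @param predicted,truth Character vectors of equal length with labels from
#'   the 7-emotion vocabulary.
#' @return List with `overall` (proportion correct) and `per_emotion` (named
#'   vector: proportion correct among recordings whose true label is that
#'   emotion; `NaN` for emotions absent from `truth`).
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(predicted) == length(truth))
  correct <- predicted == truth
  per <- vapply(emotions(), function(e) {
    idx <- truth == e
    if (!any(idx)) return(NaN)
    mean(correct[idx])
  }, numeric(1))
  list(overall = mean(correct), per_emotion = per)
}

#' Confusion matrix over the 7 emotions
#'
#' @param predicted,truth Label vectors from the 7-emotion vocabulary.
#' @param normalize_rows If `TRUE` (default), each row (true label) is
#'   divided by its count so rows sum to 1; rows for absent classes are all
#'   zero. If `FALSE`, raw counts.
#' @return 7 x 7 matrix, rows = true label, columns = predicted label, both
#'   in canonical emotion order.
#' @export
confusion_matrix <- function(predicted, truth, normalize_rows = TRUE) {
  stopifnot(length(predicted) == length(truth))
  bad <- setdiff(unique(c(predicted, truth)), emotions())
  if (length(bad)) stop("unknown label: ", bad[1], call. = FALSE)
  f <- function(x) factor(x, levels = emotions())
  m <- table(truth = f(truth), predicted = f(predicted))
  m <- unclass(m)
  if (normalize_rows) {
    rs <- rowSums(m)
    m <- m / ifelse(rs > 0, rs, 1)
  }
  m
}

#' One-vs-rest ROC AUC per emotion
#'
#' For each emotion, treats recordings of that emotion as positives and all
#' others as negatives, ranked by that emotion's score (e.g. the
#' recording-level mean cosine similarity to its prototype). AUC is computed
#' by the rank (Mann-Whitney) formula; tied scores contribute 1/2 via
#' midranks. Emotions with no positives or no negatives get `NA`.
#'
#' @param scores Numeric matrix, recordings x 7, columns in canonical
#'   emotion order (e.g. the `score_*` columns of [classify_cohort()]).
#' @param truth Character vector of true labels, one per row.
#' @return Named numeric vector of 7 AUCs in \[0, 1\] (or `NA`).
#' @export
roc_auc <- function(scores, truth) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 7, nrow(scores) == length(truth))
  colnames(scores) <- emotions()
  vapply(emotions(), function(e) {
    pos <- truth == e
    n_pos <- sum(pos)
    n_neg <- sum(!pos)
    if (n_pos == 0 || n_neg == 0) return(NA_real_)
    r <- rank(scores[, e])  # midranks handle ties
    (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }, numeric(1))
}

#' Krippendorff's alpha for nominal ratings
#'
#' Chance-corrected inter-rater agreement, `alpha = 1 - D_o / D_e`, computed
#' from the coincidence matrix with the nominal disagreement metric
#' (disagreement 1 for any two different labels). Items rated by fewer than
#' two raters are dropped; missing ratings (`NA`) are allowed.
#'
#' @param ratings Matrix or data frame, items x raters, of categorical labels
#'   (`NA` = missing); or a long data frame with columns `rater_id`,
#'   `recording_id`, `label`, which is reshaped automatically.
#' @return Scalar alpha in \[-1, 1\]. 1 = perfect agreement, 0 = agreement
#'   expected by chance.
#' @export
#' @examples
#' r <- cbind(c("joy", "fear", "anger"), c("joy", "fear", "anger"))
#' krippendorff_alpha(r)  # 1
krippendorff_alpha <- function(ratings) {
  if (is.data.frame(ratings) &&
      all(c("rater_id", "recording_id", "label") %in% names(ratings))) {
    ratings <- .rater_table_to_matrix(ratings)
  }
  m <- as.matrix(ratings)
  keep <- rowSums(!is.na(m)) >= 2
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) stop("no item with >= 2 ratings", call. = FALSE)
  cats <- sort(unique(stats::na.omit(as.vector(m))))
  k <- length(cats)
  if (k < 2) return(1)  # a single category used: no disagreement possible
  # coincidence matrix: ordered pairs within items, weighted 1/(m_u - 1)
  co <- matrix(0, k, k, dimnames = list(cats, cats))
  for (u in seq_len(nrow(m))) {
    vals <- m[u, !is.na(m[u, ])]
    mu <- length(vals)
    idx <- match(vals, cats)
    tab <- tabulate(idx, nbins = k)
    pair <- outer(tab, tab) - diag(tab)
    co <- co + pair / (mu - 1)
  }
  n_c <- rowSums(co)
  n <- sum(n_c)
  d_o <- sum(co) - sum(diag(co))            # observed off-diagonal mass
  d_e <- (sum(outer(n_c, n_c)) - sum(n_c^2)) / (n - 1)
  if (d_e == 0) return(1)
  1 - d_o / d_e
}

# long rater table -> items x raters matrix
.rater_table_to_matrix <- function(df) {
  items <- unique(df$recording_id)
  raters <- unique(df$rater_id)
  m <- matrix(NA_character_, length(items), length(raters),
              dimnames = list(items, raters))
  m[cbind(match(df$recording_id, items), match(df$rater_id, raters))] <-
    as.character(df$label)
  m
}

#' Evaluate a table of predictions
#'
#' Bundles accuracy, the row-normalized confusion matrix, one-vs-rest AUCs,
#' and (when a rater table is given) Krippendorff's alpha and the raters'
#' own accuracy against the instructed labels.
#'
#' @param predictions Data frame from [classify_cohort()].
#' @param raters Optional rater table (`rater_id`, `recording_id`, `label`).
#' @return An object of class `evaluation_report`: list with
#'   `overall_accuracy`, `per_emotion_accuracy`, `confusion`
#'   (row-normalized), `confusion_counts`, `auc`, `alpha` (or `NA`),
#'   `rater_accuracy` (or `NULL`), `n`, `method`.
#' @export
evaluate_predictions <- function(predictions, raters = NULL) {
  acc <- accuracy(predictions$predicted, predictions$truth)
  scores <- as.matrix(predictions[, paste0("score_", emotions())])
  rep <- list(
    overall_accuracy = acc$overall,
    per_emotion_accuracy = acc$per_emotion,
    confusion = confusion_matrix(predictions$predicted, predictions$truth),
    confusion_counts = confusion_matrix(predictions$predicted,
                                        predictions$truth,
                                        normalize_rows = FALSE),
    auc = roc_auc(scores, predictions$truth),
    alpha = NA_real_,
    rater_accuracy = NULL,
    n = nrow(predictions),
    method = attr(predictions, "predictions")[[1]]$method
  )
  if (!is.null(raters)) {
    rep$alpha <- krippendorff_alpha(raters)
    truth_by_id <- stats::setNames(predictions$truth,
                                   predictions$recording_id)
    known <- raters$recording_id %in% names(truth_by_id)
    r <- raters[known, ]
    ok <- r$label == truth_by_id[r$recording_id]
    rep$rater_accuracy <- c(
      tapply(ok, r$rater_id, mean),
      average = mean(tapply(ok, r$rater_id, mean))
    )
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s, n=%d\n", x$method, x$n))
  cat(sprintf("  overall accuracy: %.2f%%\n", 100 * x$overall_accuracy))
  cat("  per-emotion accuracy:\n")
  for (e in emotions()) {
    cat(sprintf("    %-9s %6.2f%%   AUC %s\n", e,
                100 * x$per_emotion_accuracy[[e]],
                ifelse(is.na(x$auc[[e]]), "NA",
                       sprintf("%.3f", x$auc[[e]]))))
  }
  if (!is.na(x$alpha)) {
    cat(sprintf("  Krippendorff's alpha (raters): %.3f\n", x$alpha))
  }
  invisible(x)
}

#' Write an evaluation report to a directory
#'
#' Emits plain, diff-able CSVs: `accuracy.csv` (overall + per-emotion +
#' AUC), `confusion.csv` and `confusion_counts.csv`, and `agreement.csv`
#' when rater results are present.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  acc <- data.frame(
    emotion = c("overall", emotions()),
    accuracy = c(report$overall_accuracy, report$per_emotion_accuracy),
    auc = c(NA, report$auc)
  )
  utils::write.csv(acc, file.path(dir, "accuracy.csv"), row.names = FALSE)
  utils::write.csv(data.frame(truth = rownames(report$confusion),
                              report$confusion, check.names = FALSE),
                   file.path(dir, "confusion.csv"), row.names = FALSE)
  utils::write.csv(data.frame(truth = rownames(report$confusion_counts),
                              report$confusion_counts, check.names = FALSE),
                   file.path(dir, "confusion_counts.csv"), row.names = FALSE)
  if (!is.null(report$rater_accuracy)) {
    utils::write.csv(
      data.frame(rater = names(report$rater_accuracy),
                 accuracy = as.numeric(report$rater_accuracy),
                 alpha = report$alpha),
      file.path(dir, "agreement.csv"), row.names = FALSE)
  }
  invisible(dir)
}
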