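#' Cosine similarity between two vectors
#'
#' `cosine(v, p) = (v . p) / (||v|| ||p||)`. The classifier's core metric:
#' it compares activation directions, not magnitudes, so it is invariant to
#' positive rescaling of either argument. If either vector is all-zero the
#' similarity is defined as 0 (a neutral face carries no direction).
#'
#' @param v,p Numeric vectors of equal length.
#' @return Scalar in \[-1, 1\].
#' @export
#' @examples
#' cosine_similarity(c(1, 2, 3), c(4, 5, 6))
cosine_similarity <- function(v, p) {
  stopifnot(length(v) == length(p))
  nv <- sqrt(sum(v^2))
  np <- sqrt(sum(p^2))
  if (nv == 0 || np == 0) return(0)
  sum(v * p) / (nv * np)
}

# Frame matrix (n x 52) against prototype matrix (7 x 52): n x 7 cosine
# similarities; zero-norm rows/prototypes yield 0.
.cosine_matrix <- function(frames, protos) {
  fn <- sqrt(rowSums(frames^2))
  pn <- sqrt(rowSums(protos^2))
  s <- frames %*% t(protos)
  denom <- outer(fn, pn)
  out <- ifelse(denom > 0, s / denom, 0)
  colnames(out) <- rownames(protos)
  out
}

#' Fit per-emotion prototype vectors
#'
#' A prototype is the elementwise mean standardized blend shape vector over
#' all sustained-phase frames of all recordings of one emotion. In
#' `"in_sample"` mode a single set of 7 prototypes is fit on the whole
#' cohort; in `"leave_one_subject_out"` mode (default) one prototype set is
#' fit per subject, excluding all of that subject's frames, so a subject is
#' never classified against prototypes containing their own data.
#'
#' @param cohort A standardized, sustained-phase [bs_cohort()] whose labels
#'   are the 7 emotions (other labels are ignored with a warning).
#' @param mode `"leave_one_subject_out"` (default) or `"in_sample"`.
#' @return An object of class `prototype_set`. For in-sample fits, element
#'   `prototypes` is a 7 x 52 matrix (rows in canonical emotion order); for
#'   LOSO fits, element `by_subject` is a named list of such matrices, one
#'   per held-out subject, and `prototypes` holds the all-data matrix for
#'   reference.
#' @export
fit_prototypes <- function(cohort,
                           mode = c("leave_one_subject_out", "in_sample")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "bs_cohort"))
  info <- cohort_info(cohort)
  is_emo <- info$label %in% emotions()
  if (!all(is_emo)) {
    warning("ignoring ", sum(!is_emo), " non-emotion recordings",
            call. = FALSE)
  }
  recs <- cohort$recordings[is_emo]
  labs <- info$label[is_emo]
  subs <- info$subject_id[is_emo]
  if (!all(vapply(recs, `[[`, logical(1), "standardized"))) {
    warning("fitting prototypes on non-standardized recordings", call. = FALSE)
  }
  missing <- setdiff(emotions(), labs)
  if (length(missing)) {
    stop("no recordings for emotion: ", missing[1], call. = FALSE)
  }
  reg <- arkit_blendshapes()
  # sufficient statistics: per (emotion, subject) frame sums and counts
  keys <- paste(labs, subs, sep = "\r")
  sums <- rowsum(
    do.call(rbind, lapply(recs, function(r) {
      c(colSums(r$values), n = n_frames(r))
    })),
    group = keys
  )
  key_emo <- sub("\r.*$", "", rownames(sums))
  key_sub <- sub("^.*\r", "", rownames(sums))
  proto_from <- function(exclude_subject = NULL) {
    keep <- if (is.null(exclude_subject)) rep(TRUE, nrow(sums))
            else key_sub != exclude_subject
    p <- matrix(NA_real_, 7, length(reg),
                dimnames = list(emotions(), reg))
    for (e in emotions()) {
      rows <- keep & key_emo == e
      ntot <- sum(sums[rows, "n"])
      if (ntot == 0) {
        stop("no training frames for emotion ", e,
             if (!is.null(exclude_subject))
               paste0(" when holding out subject ", exclude_subject),
             call. = FALSE)
      }
      p[e, ] <- colSums(sums[rows, reg, drop = FALSE]) / ntot
    }
    p
  }
  full <- proto_from(NULL)
  if (any(sqrt(rowSums(full^2)) == 0)) {
    warning("zero-norm prototype fitted", call. = FALSE)
  }
  out <- list(prototypes = full, fit_mode = mode)
  if (mode == "leave_one_subject_out") {
    subjects <- unique(subs)
    out$by_subject <- stats::setNames(
      lapply(subjects, proto_from), subjects)
  }
  structure(out, class = "prototype_set")
}

#' @export
print.prototype_set <- function(x, ...) {
  cat(sprintf("<prototype_set> fit_mode=%s, 7 x %d%s\n", x$fit_mode,
              ncol(x$prototypes),
              if (!is.null(x$by_subject))
                sprintf(", %d held-out subjects", length(x$by_subject))
              else ""))
  invisible(x)
}

# Prototype matrix to score a given subject against.
.protos_for_subject <- function(prototypes, subject_id) {
  if (identical(prototypes$fit_mode, "leave_one_subject_out")) {
    p <- prototypes$by_subject[[subject_id]]
    if (is.null(p)) {
      # unseen subject: no leakage possible, use the full-data prototypes
      p <- prototypes$prototypes
    }
    p
  } else {
    prototypes$prototypes
  }
}

#' Classify one standardized frame
#'
#' Computes the cosine similarity of the frame vector to each of the 7
#' emotion prototypes and returns the argmax. Ties (including the all-zero
#' frame, whose similarities are all 0) are broken by canonical emotion
#' order and flagged ambiguous.
#'
#' @param v Numeric vector of 52 standardized coefficients (names optional;
#'   if named, reordered to registry order).
#' @param prototypes A `prototype_set` (in-sample fit, or supply
#'   `subject_id` to select a LOSO matrix).
#' @param subject_id For LOSO prototype sets, the subject the frame belongs
#'   to.
#' @return List with `emotion`, `scores` (named length-7 vector), and
#'   `ambiguous` (logical).
#' @export
classify_frame <- function(v, prototypes, subject_id = NULL) {
  stopifnot(inherits(prototypes, "prototype_set"))
  if (!is.null(names(v))) v <- v[arkit_blendshapes()]
  p <- if (is.null(subject_id)) prototypes$prototypes
       else .protos_for_subject(prototypes, subject_id)
  s <- drop(.cosine_matrix(matrix(v, nrow = 1), p))
  best <- which(s == max(s))
  list(
    emotion = emotions()[best[1]],
    scores = s,
    ambiguous = length(best) > 1
  )
}

#' Classify a recording with the cosine prototype classifier
#'
#' Scores every sustained-phase frame against the 7 prototypes and
#' aggregates to a recording-level label: `"mean_score"` (default) takes the
#' argmax of the per-emotion mean frame similarity; `"frame_vote"` takes the
#' majority vote over per-frame argmax labels. Ties are broken by canonical
#' emotion order and flagged.
#'
#' @param rec A standardized [bs_recording()].
#' @param prototypes A `prototype_set`; LOSO sets select the matrix for
#'   `rec$subject_id` automatically.
#' @param aggregation `"mean_score"` or `"frame_vote"`.
#' @return An object of class `bs_prediction`: list with `recording_id`,
#'   `subject_id`, `truth`, `predicted`, `scores` (length-7 recording-level
#'   score vector), `frame_scores` (frames x 7 matrix), `ambiguous`,
#'   `method`.
#' @export
classify_recording <- function(rec, prototypes,
                               aggregation = c("mean_score", "frame_vote")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(rec, "bs_recording"),
            inherits(prototypes, "prototype_set"))
  if (n_frames(rec) == 0L) stop("empty recording", call. = FALSE)
  p <- .protos_for_subject(prototypes, rec$subject_id)
  fs <- .cosine_matrix(rec$values, p)
  if (aggregation == "mean_score") {
    scores <- colMeans(fs)
    best <- which(scores == max(scores))
  } else {
    frame_lab <- max.col(fs, ties.method = "first")
    votes <- tabulate(frame_lab, nbins = 7)
    scores <- stats::setNames(votes / nrow(fs), emotions())
    best <- which(votes == max(votes))
  }
  structure(
    list(
      recording_id = rec$id, subject_id = rec$subject_id, truth = rec$label,
      predicted = emotions()[best[1]],
      scores = stats::setNames(as.numeric(scores), emotions()),
      frame_scores = fs,
      ambiguous = length(best) > 1,
      method = paste0("cosine_", aggregation)
    ),
    class = "bs_prediction"
  )
}

#' Classify a recording with the mean-activation baseline
#'
#' For each emotion, averages the recording's values over frames and over
#' that emotion's EMFACS-relevant blend shapes; the emotion with the highest
#' mean activation wins. Contempt, being unilateral, is scored as the
#' maximum of its left-variant and right-variant means. Ties are broken by
#' canonical emotion order and flagged.
#'
#' @param rec A [bs_recording()] (raw or standardized; the baseline is
#'   typically run on the same standardized frames as the cosine method, but
#'   raw values are accepted for a scale-sensitive variant).
#' @param emfacs An [emfacs_table()].
#' @return A `bs_prediction` (no per-frame score matrix).
#' @export
baseline_classify_recording <- function(rec, emfacs = emfacs_table()) {
  stopifnot(inherits(rec, "bs_recording"), inherits(emfacs, "emfacs_table"))
  if (n_frames(rec) == 0L) stop("empty recording", call. = FALSE)
  shape_means <- colMeans(rec$values)
  scores <- vapply(emotions(), function(e) {
    if (e == "contempt") {
      max(mean(shape_means[emfacs$contempt_variants$left]),
          mean(shape_means[emfacs$contempt_variants$right]))
    } else {
      mean(shape_means[names(emfacs$mapping[[e]])])
    }
  }, numeric(1))
  best <- which(scores == max(scores))
  structure(
    list(
      recording_id = rec$id, subject_id = rec$subject_id, truth = rec$label,
      predicted = emotions()[best[1]],
      scores = scores,
      frame_scores = NULL,
      ambiguous = length(best) > 1,
      method = "baseline_mean_activation"
    ),
    class = "bs_prediction"
  )
}

#' @export
print.bs_prediction <- function(x, ...) {
  cat(sprintf("<bs_prediction %s> %s -> %s (%s)%s\n", x$recording_id,
              x$truth, x$predicted, x$method,
              if (x$ambiguous) " [ambiguous]" else ""))
  invisible(x)
}

#' Classify every emotion recording of a cohort
#'
#' @param cohort A standardized, sustained-phase [bs_cohort()]; non-emotion
#'   recordings are skipped.
#' @param prototypes A `prototype_set` (required for `method = "cosine"`).
#' @param method `"cosine"` or `"baseline"`.
#' @param aggregation Passed to [classify_recording()] for the cosine method.
#' @param emfacs Passed to [baseline_classify_recording()].
#' @return Data frame with one row per recording: `recording_id`,
#'   `subject_id`, `truth`, `predicted`, `ambiguous`, and one `score_<emotion>`
#'   column per emotion. The list of full `bs_prediction` objects is attached
#'   as attribute `"predictions"`.
#' @export
classify_cohort <- function(cohort, prototypes = NULL,
                            method = c("cosine", "baseline"),
                            aggregation = "mean_score",
                            emfacs = emfacs_table()) {
  method <- match.arg(method)
  info <- cohort_info(cohort)
  recs <- cohort$recordings[info$label %in% emotions()]
  if (!length(recs)) stop("no emotion recordings in cohort", call. = FALSE)
  preds <- lapply(recs, function(r) {
    if (method == "cosine") {
      if (is.null(prototypes)) {
        stop("cosine method requires prototypes", call. = FALSE)
      }
      classify_recording(r, prototypes, aggregation = aggregation)
    } else {
      baseline_classify_recording(r, emfacs = emfacs)
    }
  })
  scores <- do.call(rbind, lapply(preds, `[[`, "scores"))
  colnames(scores) <- paste0("score_", emotions())
  out <- data.frame(
    recording_id = vapply(preds, `[[`, character(1), "recording_id"),
    subject_id = vapply(preds, `[[`, character(1), "subject_id"),
    truth = vapply(preds, `[[`, character(1), "truth"),
    predicted = vapply(preds, `[[`, character(1), "predicted"),
    ambiguous = vapply(preds, `[[`, logical(1), "ambiguous"),
    row.names = NULL
  )
  out <- cbind(out, as.data.frame(scores, row.names = NULL))
  attr(out, "predictions") <- preds
  out
}

#' Save prototypes as CSV
#'
#' Writes a 7 x 52 table (one row per emotion in canonical order, columns in
#' registry order) readable by [read_prototypes()]; the portable on-device
#' representation of a fitted classifier.
#'
#' @param prototypes A `prototype_set` (the full-data matrix is written).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_prototypes <- function(prototypes, path) {
  stopifnot(inherits(prototypes, "prototype_set"))
  df <- data.frame(emotion = rownames(prototypes$prototypes),
                   prototypes$prototypes, check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read prototypes from CSV
#'
#' @param path CSV written by [write_prototypes()].
#' @return An in-sample `prototype_set`.
#' @export
read_prototypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(identical(df$emotion, emotions()),
            all(arkit_blendshapes() %in% names(df)))
  m <- as.matrix(df[, arkit_blendshapes()])
  rownames(m) <- df$emotion
  structure(list(prototypes = m, fit_mode = "in_sample"),
            class = "prototype_set")
}
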