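#' Construct a blend shape recording
#'
#' A recording is an ordered sequence of frames, each holding the 52 ARKit
#' blend shape coefficients, together with its metadata: subject, target
#' expression label, and nominal frame rate.
#'
#' @param values Numeric matrix, frames x 52, with column names equal to
#'   [arkit_blendshapes()] (any column order is accepted and reordered).
#' @param t Numeric vector of frame times in seconds since recording start,
#'   non-decreasing, one per row of `values`.
#' @param subject_id Character scalar identifying the subject.
#' @param label Target expression: one of the 7 emotions ([emotions()]) or
#'   one of the 36 movement names ([movement_labels()]).
#' @param fps Nominal frame rate, 30 or 60.
#' @param standardized Logical; `FALSE` for raw captures (values must lie in
#'   \[0, 1\]), `TRUE` after z-scoring (range bound not enforced).
#' @param id Optional recording identifier; defaults to
#'   `<subject_id>_<label>`.
#' @return An object of class `bs_recording`.
#' @export
#' @examples
#' v <- matrix(0.1, nrow = 3, ncol = 52,
#'             dimnames = list(NULL, arkit_blendshapes()))
#' rec <- bs_recording(v, t = c(0, 1, 2) / 30, "s01", "joy", fps = 30)
#' rec
bs_recording <- function(values, t, subject_id, label, fps,
                         standardized = FALSE, id = NULL) {
  reg <- arkit_blendshapes()
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(colnames(values))) {
    stop("values matrix must have blend shape column names", call. = FALSE)
  }
  missing <- setdiff(reg, colnames(values))
  if (length(missing)) {
    stop("missing column ", missing[1], call. = FALSE)
  }
  values <- values[, reg, drop = FALSE]
  storage.mode(values) <- "double"
  if (nrow(values) == 0L) stop("empty recording", call. = FALSE)
  if (length(t) != nrow(values)) {
    stop("t must have one entry per frame", call. = FALSE)
  }
  if (is.unsorted(t)) stop("frame times must be non-decreasing", call. = FALSE)
  if (!fps %in% c(30, 60)) stop("fps must be 30 or 60", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite value at row ", bad[["row"]], call. = FALSE)
  }
  if (!standardized && (any(values < 0) || any(values > 1))) {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)[1, ]
    stop("value out of [0,1] at row ", bad[["row"]],
         " (", colnames(values)[bad[["col"]]], ")", call. = FALSE)
  }
  vocab <- c(emotions(), movement_labels())
  if (!label %in% vocab) {
    stop("unknown label: ", label, call. = FALSE)
  }
  structure(
    list(
      id = if (is.null(id)) paste(subject_id, label, sep = "_") else id,
      subject_id = as.character(subject_id),
      label = label,
      fps = as.numeric(fps),
      t = as.numeric(t),
      values = values,
      standardized = isTRUE(standardized)
    ),
    class = "bs_recording"
  )
}

#' @export
print.bs_recording <- function(x, ...) {
  cat(sprintf(
    "<bs_recording %s> subject=%s label=%s fps=%g frames=%d duration=%.3fs%s\n",
    x$id, x$subject_id, x$label, x$fps, n_frames(x), duration(x),
    if (x$standardized) " [standardized]" else ""
  ))
  invisible(x)
}

#' Number of frames in a recording
#' @param rec A `bs_recording`.
#' @return Integer frame count.
#' @export
n_frames <- function(rec) nrow(rec$values)

#' Recording duration in seconds
#' @param rec A `bs_recording`.
#' @return Time span from the first to the last frame plus one frame period.
#' @export
duration <- function(rec) {
  diff(range(rec$t)) + 1 / rec$fps
}

#' Construct a cohort of recordings
#'
#' @param recordings List of [bs_recording()] objects with unique ids.
#' @param raters Optional data frame of human labels with columns
#'   `rater_id`, `recording_id`, `label`; every `recording_id` must exist in
#'   `recordings`.
#' @return An object of class `bs_cohort`.
#' @export
bs_cohort <- function(recordings, raters = NULL) {
  stopifnot(is.list(recordings), length(recordings) > 0)
  ok <- vapply(recordings, inherits, logical(1), "bs_recording")
  if (!all(ok)) stop("all elements must be bs_recording objects", call. = FALSE)
  ids <- vapply(recordings, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate recording ids: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  names(recordings) <- ids
  if (!is.null(raters)) {
    raters <- as.data.frame(raters)
    need <- c("rater_id", "recording_id", "label")
    if (!all(need %in% names(raters))) {
      stop("raters table needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    unknown <- setdiff(raters$recording_id, ids)
    if (length(unknown)) {
      stop("rater labels reference unknown recording: ", unknown[1],
           call. = FALSE)
    }
  }
  structure(list(recordings = recordings, raters = raters),
            class = "bs_cohort")
}

#' @export
print.bs_cohort <- function(x, ...) {
  labs <- vapply(x$recordings, `[[`, character(1), "label")
  subj <- vapply(x$recordings, `[[`, character(1), "subject_id")
  cat(sprintf("<bs_cohort> %d recordings, %d subjects, %d labels%s\n",
              length(x$recordings), length(unique(subj)),
              length(unique(labs)),
              if (is.null(x$raters)) "" else
                sprintf(", %d rater labels", nrow(x$raters))))
  invisible(x)
}

#' @export
length.bs_cohort <- function(x) length(x$recordings)

#' Apply a function to every recording in a cohort
#'
#' @param cohort A `bs_cohort`.
#' @param f Function taking and returning a `bs_recording`.
#' @param ... Passed on to `f`.
#' @return A `bs_cohort` with transformed recordings (rater table preserved).
#' @export
cohort_map <- function(cohort, f, ...) {
  recs <- lapply(cohort$recordings, f, ...)
  bs_cohort(recs, raters = cohort$raters)
}

#' Subject, label and id metadata of a cohort
#'
#' @param cohort A `bs_cohort`.
#' @return Data frame with one row per recording: `recording_id`,
#'   `subject_id`, `label`, `fps`, `n_frames`.
#' @export
cohort_info <- function(cohort) {
  data.frame(
    recording_id = vapply(cohort$recordings, `[[`, character(1), "id"),
    subject_id = vapply(cohort$recordings, `[[`, character(1), "subject_id"),
    label = vapply(cohort$recordings, `[[`, character(1), "label"),
    fps = vapply(cohort$recordings, `[[`, numeric(1), "fps"),
    n_frames = vapply(cohort$recordings, n_frames, integer(1)),
    row.names = NULL
  )
}

#' Read a per-recording blend shape CSV
#'
#' The CSV dialect matches the capture app's export: a header row, one `t`
#' column holding seconds since recording start (millisecond precision or
#' better), and one column per blend shape named exactly as in
#' [arkit_blendshapes()]. Extra columns are ignored with a warning.
#'
#' @param path CSV file path.
#' @param subject_id,label,fps Recording metadata (see [bs_recording()]).
#' @param standardized Logical; set `TRUE` when reading z-scored values.
#' @param id Optional recording id.
#' @return A [bs_recording()].
#' @export
read_recording_csv <- function(path, subject_id, label, fps,
                               standardized = FALSE, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"t" %in% names(df)) stop("missing column t", call. = FALSE)
  reg <- arkit_blendshapes()
  missing <- setdiff(reg, names(df))
  if (length(missing)) {
    stop("missing column ", missing[1], call. = FALSE)
  }
  extra <- setdiff(names(df), c("t", reg))
  if (length(extra)) {
    warning("ignoring extra columns: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  vals <- df[, reg, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum)) {
    col <- names(vals)[nonnum][1]
    row <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
    stop("non-numeric value in column ", col, " at row ",
         if (is.na(row)) "?" else row, call. = FALSE)
  }
  ord <- order(df$t)
  bs_recording(as.matrix(vals)[ord, , drop = FALSE], t = df$t[ord],
               subject_id = subject_id, label = label, fps = fps,
               standardized = standardized, id = id)
}

#' Write a recording to CSV
#'
#' Writes the canonical dialect read back by [read_recording_csv()]: a `t`
#' column followed by the 52 blend shape columns in registry order, at full
#' double precision so that write/read round-trips are exact.
#'
#' @param rec A [bs_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "bs_recording"))
  if (n_frames(rec) == 0L) stop("empty recording", call. = FALSE)
  df <- data.frame(t = rec$t, rec$values, check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort to a directory with a manifest
#'
#' Each recording goes to `<dir>/<recording_id>.csv`; a `manifest.csv` lists
#' `path`, `subject_id`, `label`, `fps`, `standardized` per recording, and an
#' optional `raters.csv` holds the human label table.
#'
#' @param cohort A [bs_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  info <- cohort_info(cohort)
  paths <- file.path(dir, paste0(info$recording_id, ".csv"))
  for (i in seq_along(cohort$recordings)) {
    write_recording_csv(cohort$recordings[[i]], paths[i])
  }
  man <- data.frame(
    path = basename(paths),
    subject_id = info$subject_id,
    label = info$label,
    fps = info$fps,
    standardized = vapply(cohort$recordings, `[[`, logical(1), "standardized")
  )
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$raters)) {
    utils::write.csv(cohort$raters, file.path(dir, "raters.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(man_path)
}

#' Read a cohort from a manifest
#'
#' @param manifest Path to a `manifest.csv` written by [write_cohort()] (or
#'   hand-authored with the same columns); recording paths are resolved
#'   relative to the manifest's directory.
#' @return A [bs_cohort()]; a `raters.csv` next to the manifest is attached
#'   automatically.
#' @export
read_cohort <- function(manifest) {
  if (!file.exists(manifest)) {
    stop("manifest not found: ", manifest, call. = FALSE)
  }
  man <- utils::read.csv(manifest)
  base <- dirname(manifest)
  std <- if ("standardized" %in% names(man)) man$standardized else FALSE
  std <- rep_len(std, nrow(man))
  recs <- lapply(seq_len(nrow(man)), function(i) {
    read_recording_csv(file.path(base, man$path[i]),
                       subject_id = man$subject_id[i], label = man$label[i],
                       fps = man$fps[i], standardized = std[i],
                       id = sub("\\.csv$", "", basename(man$path[i])))
  })
  raters <- NULL
  rp <- file.path(base, "raters.csv")
  if (file.exists(rp)) {
    raters <- utils::read.csv(rp, colClasses = "character")
  }
  bs_cohort(recs, raters = raters)
}
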