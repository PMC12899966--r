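#' Per-blend-shape range summary
#'
#' Minimum, mean and maximum of every blend shape over all frames of all
#' recordings in a cohort, on the raw \[0, 1\] scale.
#'
#' @param cohort A raw [bs_cohort()].
#' @return Data frame with columns `blendshape`, `min`, `mean`, `max`
#'   (52 rows, registry order).
#' @export
range_summary <- function(cohort) {
  stopifnot(inherits(cohort, "bs_cohort"))
  x <- do.call(rbind, lapply(cohort$recordings, `[[`, "values"))
  if (is.null(x) || nrow(x) == 0) stop("empty cohort", call. = FALSE)
  data.frame(
    blendshape = arkit_blendshapes(),
    min = apply(x, 2, min),
    mean = colMeans(x),
    max = apply(x, 2, max),
    row.names = NULL
  )
}

#' Co-activation overlap of blend shape pairs
#'
#' For each pair `(x, y)`, the fraction of frames in which both blend shapes
#' are simultaneously active (`x > eps` and `y > eps`), over all frames of
#' the cohort. Operates on raw values: after z-scoring roughly half of all
#' values are positive by construction, which would make "activated"
#' meaningless.
#'
#' @param cohort A raw [bs_cohort()].
#' @param pairs Data frame with columns `blendshape_1`, `blendshape_2`
#'   (default: the 12 [opposite_pairs()]).
#' @param eps Activation threshold; a value counts as active when strictly
#'   greater than `eps` (default 0, exact as defined; raise for
#'   floating-point capture noise).
#' @return Data frame: `blendshape_1`, `blendshape_2`, `overlap` in \[0, 1\],
#'   `n_frames`.
#' @export
pair_overlap <- function(cohort, pairs = opposite_pairs(), eps = 0) {
  stopifnot(inherits(cohort, "bs_cohort"))
  bad <- setdiff(c(pairs$blendshape_1, pairs$blendshape_2),
                 arkit_blendshapes())
  if (length(bad)) stop("unknown blend shape: ", bad[1], call. = FALSE)
  x <- do.call(rbind, lapply(cohort$recordings, `[[`, "values"))
  n <- nrow(x)
  ov <- mapply(function(a, b) sum(x[, a] > eps & x[, b] > eps) / n,
               pairs$blendshape_1, pairs$blendshape_2)
  data.frame(
    blendshape_1 = pairs$blendshape_1,
    blendshape_2 = pairs$blendshape_2,
    overlap = as.numeric(ov),
    n_frames = n,
    row.names = NULL
  )
}

#' Facial-region co-activation (Spearman)
#'
#' Aggregates each facial region (jaw, eye, mouth, cheek, brow, nose,
#' tongue) as the per-frame arithmetic mean of its member blend shapes, then
#' computes Spearman rank correlations between the seven region series
#' across all frames of the cohort, with p-values.
#'
#' @param cohort A raw [bs_cohort()].
#' @return List with `rho` (7 x 7 symmetric correlation matrix, diagonal 1;
#'   `NA` where a region series is constant) and `p` (matching p-value
#'   matrix, `NA` on the diagonal).
#' @export
region_coactivation <- function(cohort) {
  stopifnot(inherits(cohort, "bs_cohort"))
  x <- do.call(rbind, lapply(cohort$recordings, `[[`, "values"))
  if (nrow(x) < 3) stop("need at least 3 frames", call. = FALSE)
  reg <- blendshape_regions()
  regions <- c("jaw", "eye", "mouth", "cheek", "brow", "nose", "tongue")
  agg <- vapply(regions, function(r) {
    rowMeans(x[, names(reg)[reg == r], drop = FALSE])
  }, numeric(nrow(x)))
  k <- length(regions)
  rho <- matrix(NA_real_, k, k, dimnames = list(regions, regions))
  p <- matrix(NA_real_, k, k, dimnames = list(regions, regions))
  diag(rho) <- 1
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      a <- agg[, i]; b <- agg[, j]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next  # undefined
      ct <- suppressWarnings(
        stats::cor.test(a, b, method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p = p)
}

#' Write descriptive tables to a directory
#'
#' Emits `range_summary.csv`, `pair_overlap.csv`, `region_correlation.csv`
#' and `region_correlation_p.csv`.
#'
#' @param cohort A raw [bs_cohort()].
#' @param dir Output directory (created if needed).
#' @param eps Passed to [pair_overlap()].
#' @return `dir`, invisibly.
#' @export
describe_cohort <- function(cohort, dir = NULL, eps = 0) {
  rs <- range_summary(cohort)
  ov <- pair_overlap(cohort, eps = eps)
  rc <- region_coactivation(cohort)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rs, file.path(dir, "range_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(ov, file.path(dir, "pair_overlap.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(region = rownames(rc$rho), rc$rho),
                     file.path(dir, "region_correlation.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(region = rownames(rc$p), rc$p),
                     file.path(dir, "region_correlation_p.csv"),
                     row.names = FALSE)
  }
  invisible(list(range_summary = rs, pair_overlap = ov,
                 region_coactivation = rc))
}
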