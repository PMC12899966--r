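# Independent brute-force oracles. These deliberately avoid the package's
# own computation paths: plain loops and first-principles formulas only.

oracle_cosine <- function(v, p) {
  num <- 0; nv <- 0; np <- 0
  for (i in seq_along(v)) {
    num <- num + v[i] * p[i]
    nv <- nv + v[i]^2
    np <- np + p[i]^2
  }
  num / (sqrt(nv) * sqrt(np))
}

# one-vs-rest AUC by exhaustive pairwise comparison, ties = 1/2
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (a in pos) {
    for (b in neg) {
      total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Krippendorff's alpha (nominal) directly from within-item ordered pairs:
# D_o = (1/n) sum_u sum_{i != j in u} delta(c_i, c_j) / (m_u - 1),
# D_e from all cross-item pairable values.
oracle_alpha <- function(m) {
  m <- as.matrix(m)
  m <- m[rowSums(!is.na(m)) >= 2, , drop = FALSE]
  vals_by_item <- apply(m, 1, function(r) r[!is.na(r)], simplify = FALSE)
  d_o <- 0; n <- 0
  pooled <- character(0)
  for (vals in vals_by_item) {
    mu <- length(vals)
    n <- n + mu
    pooled <- c(pooled, vals)
    for (i in seq_len(mu)) {
      for (j in seq_len(mu)) {
        if (i != j && vals[i] != vals[j]) d_o <- d_o + 1 / (mu - 1)
      }
    }
  }
  d_o <- d_o / n
  d_e <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && pooled[i] != pooled[j]) d_e <- d_e + 1
    }
  }
  d_e <- d_e / (n * (n - 1))
  1 - d_o / d_e
}

# population (ddof = 0) z-score from the direct formula
oracle_zscore <- function(x) {
  mu <- sum(x) / length(x)
  sd <- sqrt(sum((x - mu)^2) / length(x))
  if (sd == 0) rep(0, length(x)) else (x - mu) / sd
}

random_frame <- function(standardized = TRUE) {
  v <- if (standardized) stats::rnorm(52) else stats::runif(52)
  stats::setNames(v, arkit_blendshapes())
}

# small random raw recording
random_recording <- function(n = 10, subject_id = "s01", label = "joy",
                             fps = 30, standardized = FALSE) {
  vals <- matrix(if (standardized) stats::rnorm(n * 52)
                 else stats::runif(n * 52),
                 n, 52, dimnames = list(NULL, arkit_blendshapes()))
  bs_recording(vals, t = (seq_len(n) - 1) / fps, subject_id = subject_id,
               label = label, fps = fps, standardized = standardized)
}

# tiny cohort: n_subjects x emotions, a few frames each
random_cohort <- function(n_subjects = 2, n = 6, standardized = FALSE) {
  recs <- list()
  for (s in seq_len(n_subjects)) {
    for (e in emotions()) {
      recs[[length(recs) + 1]] <- random_recording(
        n = n, subject_id = sprintf("s%02d", s), label = e,
        standardized = standardized)
    }
  }
  bs_cohort(recs)
}
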