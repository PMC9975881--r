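#' Build a children-by-feature matrix from a cohort feature table
#'
#' Pivots the long feature table (one row per child, activity, keypoint) into
#' a wide matrix whose rows are children and whose columns are named
#' `<activity>|kp<keypoint>|<feature>`. Missing cells stay NA and are handled
#' pairwise-complete downstream.
#'
#' @param feature_table tibble with columns `child_id`, `activity`,
#'   `keypoint`, `L_mean`, `L_std`, `dL_mean`, `dL_std`.
#' @param scores score tibble (`child_id`, `activity_level_score`); row order
#'   of the matrix follows this table.
#' @return list `x` (numeric matrix), `scores` (integer vector aligned with
#'   rows), `info` (tibble mapping columns to activity / keypoint / feature).
#' @export
feature_matrix <- function(feature_table, scores) {
  feats <- c("L_mean", "L_std", "dL_mean", "dL_std")
  key <- unique(feature_table[c("activity", "keypoint")])
  info <- do.call(rbind, lapply(feats, function(f) {
    tibble::tibble(activity = key$activity, keypoint = key$keypoint, feature = f)
  }))
  info$column <- sprintf("%s|kp%d|%s", info$activity, info$keypoint, info$feature)
  x <- matrix(NA_real_, nrow = nrow(scores), ncol = nrow(info),
              dimnames = list(scores$child_id, info$column))
  row_of <- match(feature_table$child_id, scores$child_id)
  for (j in seq_len(nrow(info))) {
    sel <- feature_table$activity == info$activity[j] &
      feature_table$keypoint == info$keypoint[j]
    x[row_of[sel], info$column[j]] <- feature_table[[info$feature[j]]][sel]
  }
  list(x = x, scores = scores$activity_level_score, info = info)
}

#' Pairwise-complete Pearson correlation matrix
#'
#' @param x numeric matrix (children in rows, features in columns).
#' @param min_pairs minimum complete pairs per cell; cells with fewer, or
#'   with a constant margin, are NA.
#' @return correlation matrix with NA for undefined cells.
#' @export
pearson_matrix <- function(x, min_pairs = 3) {
  suppressWarnings(r <- stats::cor(x, use = "pairwise.complete.obs"))
  ok <- crossprod(!is.na(x)) >= min_pairs
  r[!ok] <- NA_real_
  r
}

#' Spearman correlation of one feature with activity-level scores
#'
#' Spearman's rho with average ranks for ties (the score vector is heavily
#' tied: only three levels). The two-sided p-value uses the t-approximation
#' t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom, which is valid
#' at the study's sample size; for n <= `exact_max` an exact permutation
#' p-value over all score permutations is available instead.
#'
#' @param x numeric feature column (NAs dropped pairwise).
#' @param scores integer scores aligned with `x`.
#' @param exact use the permutation p-value (Monte Carlo over `n_perm` random
#'   permutations, or exhaustive below `exact_max` when feasible).
#' @param n_perm permutations for the Monte Carlo p-value.
#' @return list `rho`, `p`, `n` (complete pairs). `rho` is NA when either
#'   margin is constant or fewer than 4 complete pairs exist.
#' @export
spearman_vs_scores <- function(x, scores, exact = FALSE, n_perm = 10000) {
  ok <- !is.na(x) & !is.na(scores)
  x <- x[ok]; scores <- scores[ok]
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0 || stats::sd(scores) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(scores))
  if (exact) {
    obs <- abs(rho)
    rx <- rank(x)
    perm <- replicate(n_perm, abs(stats::cor(rx, rank(sample(scores)))))
    p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Benjamini-Hochberg adjustment within families
#'
#' Step-up adjusted p-values, computed independently within each family (one
#' family per activity, matching how the study corrects its per-activity
#' correlation tables). Values are monotone over the within-family order
#' statistics and capped at 1.
#'
#' @param p numeric p-values in [0, 1].
#' @param family factor-like family labels aligned with `p`; NULL for one
#'   family.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p, family = NULL) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  if (is.null(family)) family <- rep(1L, length(p))
  stopifnot(length(family) == length(p))
  out <- rep(NA_real_, length(p))
  for (fam in unique(family)) {
    idx <- which(family == fam & !is.na(p))
    if (length(idx) > 0) out[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  out
}

#' Prune redundant movement features across keypoints
#'
#' Within each (feature, activity) block the three keypoint variants are
#' compared: when every pairwise PCC in the block is at least `threshold`
#' the variants are interchangeable and only the neck one (the most visible
#' keypoint) is retained; if any pair falls below the threshold all keypoints
#' are kept. With the study's structure this keeps neck-only PD features and
#' all three keypoints for the IPV features.
#'
#' @param pcc named list: per (feature, activity) label, the keypoint-by-
#'   keypoint PCC matrix (as from [keypoint_pcc_blocks()]).
#' @param threshold redundancy threshold in (0, 1]; default 0.95.
#' @param neck_keypoint keypoint id retained for redundant blocks.
#' @return tibble `feature`, `activity`, `keypoint`, `retained`.
#' @export
redundancy_prune <- function(pcc, threshold = 0.95, neck_keypoint = 1L) {
  stopifnot(threshold > 0, threshold <= 1)
  rows <- list()
  for (label in names(pcc)) {
    block <- pcc[[label]]
    kps <- as.integer(sub("^kp", "", colnames(block)))
    off <- block[upper.tri(block)]
    redundant <- length(off) > 0 && all(!is.na(off)) && all(off >= threshold)
    parts <- strsplit(label, "|", fixed = TRUE)[[1]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      feature = parts[1], activity = parts[2], keypoint = kps,
      retained = if (redundant) kps == neck_keypoint else rep(TRUE, length(kps)))
  }
  do.call(rbind, rows)
}

#' Keypoint-by-keypoint PCC blocks per feature and activity
#'
#' For each (feature, activity), the Pearson correlation matrix between the
#' three keypoint variants across children — the layout of the published
#' redundancy table.
#'
#' @param fm a [feature_matrix()].
#' @param activities activities to include (default: all in the matrix).
#' @return named list of PCC matrices, labels `<feature>|<activity>`.
#' @export
keypoint_pcc_blocks <- function(fm, activities = unique(fm$info$activity)) {
  out <- list()
  for (f in unique(fm$info$feature)) {
    for (act in activities) {
      cols <- fm$info$column[fm$info$feature == f & fm$info$activity == act]
      if (length(cols) < 2) next
      block <- pearson_matrix(fm$x[, cols, drop = FALSE])
      kps <- fm$info$keypoint[match(cols, fm$info$column)]
      dimnames(block) <- list(paste0("kp", kps), paste0("kp", kps))
      out[[paste0(f, "|", act)]] <- block
    }
  }
  out
}

#' Correlation power analysis
#'
#' Power to detect a population correlation `r` at two-sided level `alpha`
#' with `n` pairs, by the Fisher-z method with small-sample bias correction:
#' the effect is z_r = atanh(r) + r / (2(n-1)); the critical correlation r_c
#' comes from the t critical value at n-2 degrees of freedom via
#' r_c = sqrt(t^2 / (t^2 + n - 2)); and
#' power = Phi((z_r - atanh(r_c)) sqrt(n-3)) + Phi(-(z_r + atanh(r_c)) sqrt(n-3)).
#'
#' @param n sample size (>= 4).
#' @param r target population correlation, 0 < r < 1.
#' @param alpha significance level, 0 < alpha < 1.
#' @param two_sided logical; one-sided tests use the upper tail only.
#' @return power in (0, 1).
#' @export
correlation_power <- function(n, r, alpha, two_sided = TRUE) {
  if (n < 4) stop("n must be at least 4")
  if (r <= 0 || r >= 1) stop("r must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  df <- n - 2
  zr <- atanh(r) + r / (2 * (n - 1))
  tc <- stats::qt(1 - if (two_sided) alpha / 2 else alpha, df = df)
  zc <- atanh(sqrt(tc^2 / (tc^2 + df)))
  s <- sqrt(n - 3)
  if (two_sided) {
    stats::pnorm((zr - zc) * s) + stats::pnorm(-(zr + zc) * s)
  } else {
    stats::pnorm((zr - zc) * s)
  }
}

#' Per-comparison alpha for planned comparisons
#'
#' Splits a family-wise level evenly over k planned comparisons
#' (Bonferroni-style): with a conventional 0.05 family level and four planned
#' movement-feature correlations, the per-comparison level is 0.0125.
#'
#' @param family_alpha family-wise significance level.
#' @param k number of planned comparisons (>= 1).
#' @return `family_alpha / k`.
#' @export
alpha_for_planned_comparisons <- function(family_alpha, k) {
  if (k < 1) stop("k must be at least 1")
  stopifnot(family_alpha > 0, family_alpha < 1)
  family_alpha / k
}

#' Descriptive characteristics of a feature column
#'
#' @param x numeric values (NAs dropped); at least 2 required.
#' @return tibble `min`, `q25`, `median`, `mean`, `q75`, `max`, `sd` (sample
#'   denominator n-1; quartiles by linear interpolation), `n`.
#' @export
feature_characteristics <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 values")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(min = min(x), q25 = q[1], median = q[2], mean = mean(x),
                 q75 = q[3], max = max(x), sd = stats::sd(x), n = length(x))
}

#' Correlate every movement feature with the activity-level scores
#'
#' Computes Spearman's rho and its raw p-value for every feature column of
#' the matrix, then applies the Benjamini-Hochberg correction within each
#' activity family.
#'
#' @param fm a [feature_matrix()].
#' @return tibble `activity`, `keypoint`, `feature`, `rho`, `p_raw`, `p_bh`,
#'   `n`.
#' @export
score_correlations <- function(fm) {
  res <- lapply(seq_len(nrow(fm$info)), function(j) {
    s <- spearman_vs_scores(fm$x[, fm$info$column[j]], fm$scores)
    tibble::tibble(activity = fm$info$activity[j],
                   keypoint = fm$info$keypoint[j],
                   feature = fm$info$feature[j],
                   rho = s$rho, p_raw = s$p, n = s$n)
  })
  out <- do.call(rbind, res)
  out$p_bh <- bh_adjust(out$p_raw, out$activity)
  out[c("activity", "keypoint", "feature", "rho", "p_raw", "p_bh", "n")]
}
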