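#' Fleiss' kappa for multiple raters and two categories
#'
#' Chance-corrected agreement among a fixed panel of raters over a set of
#' items (slices), kappa = (Pbar - Pbar_e) / (1 - Pbar_e). Per-item agreement
#' is P_i = (sum_j n_ij^2 - n) / (n (n - 1)) with n raters and n_ij raters
#' choosing category j on item i; chance agreement Pbar_e = sum_j p_j^2 uses
#' the category proportions pooled over all items and raters.
#'
#' For two raters this equals Scott's pi (pooled-marginal chance), which is
#' not the same as Cohen's kappa when the two raters' marginal rates differ.
#'
#' @param labels A label table: a logical matrix (items x raters) or a tibble
#'   from [binarize_scores()] (a `slice_id` column is ignored). `TRUE` means
#'   a positive call.
#' @return The kappa value (scalar, at most 1).
#' @export
#' @examples
#' m <- cbind(a = c(TRUE, TRUE, FALSE), b = c(TRUE, TRUE, FALSE),
#'            c = c(TRUE, FALSE, FALSE))
#' fleiss_kappa(m)
fleiss_kappa <- function(labels) {
  m <- as_label_matrix(labels)
  if (ncol(m) < 2) abort("Fleiss' kappa needs at least 2 raters")
  if (nrow(m) < 2) abort("Fleiss' kappa needs at least 2 items")
  n <- ncol(m)
  pos <- rowSums(m)
  p1 <- sum(pos) / (nrow(m) * n)
  p_e <- p1^2 + (1 - p1)^2
  if (p1 == 0 || p1 == 1) {
    abort("Fleiss' kappa is undefined: every rating is in a single category")
  }
  p_i <- (pos^2 + (n - pos)^2 - n) / (n * (n - 1))
  (mean(p_i) - p_e) / (1 - p_e)
}

#' Cohen's kappa for two ratings of the same items
#'
#' kappa = (p_o - p_e) / (1 - p_e), with observed agreement p_o and chance
#' agreement p_e from the product of the two raters' marginal rates in the
#' 2x2 contingency table. Used here for intra-observer (session 1 vs session
#' 2) agreement.
#'
#' @param labels_a,labels_b Logical vectors of the same length, one element
#'   per item.
#' @return The kappa value (scalar, at most 1).
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  a <- as.logical(labels_a)
  b <- as.logical(labels_b)
  if (length(a) != length(b)) abort("label vectors must have equal length")
  if (anyNA(a) || anyNA(b)) abort("labels must not contain NA")
  p_o <- mean(a == b)
  pa <- mean(a)
  pb <- mean(b)
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  if (p_e == 1) {
    abort("Cohen's kappa is undefined: both ratings are constant and equal")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Unanimity percentage agreement for a rater group
#'
#' The percentage of items on which every rater in the group gives the same
#' label; any split vote counts as disagreement. For two raters this reduces
#' to simple pairwise percentage agreement. The reference standard plays no
#' role.
#'
#' @inheritParams fleiss_kappa
#' @return Percent in \[0, 100\].
#' @export
pct_agreement <- function(labels) {
  m <- as_label_matrix(labels)
  if (ncol(m) < 2) abort("percentage agreement needs at least 2 raters")
  pos <- rowSums(m)
  100 * mean(pos == 0L | pos == ncol(m))
}

#' Interpret a kappa value on the conventional agreement bands
#'
#' Values at or below 0 are poor agreement; above 0, 0.2, 0.4, 0.6 and 0.8
#' they are slight, fair, moderate, substantial and almost perfect (the
#' Landis-Koch convention). A boundary value belongs to the lower band, so
#' kappa = 0.2 is slight.
#'
#' @param kappa Numeric vector of kappa values in \[-1, 1\].
#' @return Character vector of band labels.
#' @export
kappa_interpretation <- function(kappa) {
  if (any(kappa < -1 | kappa > 1)) abort("kappa must lie in [-1, 1]")
  bands <- c("poor", "slight", "fair", "moderate", "substantial",
             "almost perfect")
  # boundary to the lower band: strict > at each cut
  idx <- 1L + (kappa > 0) + (kappa > 0.2) + (kappa > 0.4) + (kappa > 0.6) +
    (kappa > 0.8)
  bands[idx]
}

#' Case-resampling bootstrap confidence interval for an agreement metric
#'
#' Resamples slices (rows) with replacement, holding the observer panel
#' fixed, and reports a percentile interval. Resamples on which a kappa is
#' undefined (all ratings in one category) are dropped and counted; a warning
#' is raised if more than 1% are dropped, since the interval is then
#' conditional on the statistic being defined.
#'
#' @param labels Label table (items x raters); for `metric = "cohen_kappa"`
#'   it must have exactly two rater columns (e.g. the two reading sessions of
#'   one observer).
#' @param metric `"fleiss_kappa"`, `"pct_agreement"` or `"cohen_kappa"`.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param ci_level Confidence level (default 0.95).
#' @param seed Integer seed; results are reproducible bit-for-bit from
#'   `(seed, n_boot)`.
#' @return A one-row tibble: `metric`, `value`, `ci_low`, `ci_high`,
#'   `ci_level`, `n_boot`, `n_dropped`, `seed`.
#' @export
bootstrap_ci <- function(labels,
                         metric = c("fleiss_kappa", "pct_agreement",
                                    "cohen_kappa"),
                         n_boot = 2000L, ci_level = 0.95, seed) {
  metric <- arg_match(metric)
  stopifnot(n_boot >= 1, ci_level > 0, ci_level < 1)
  m <- as_label_matrix(labels)
  f <- metric_fun(metric)
  value <- f(m) # errors here propagate: metric undefined on observed data
  withr::local_seed(seed)
  stat <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(m), nrow(m), replace = TRUE)
    stat[b] <- tryCatch(f(m[idx, , drop = FALSE]), error = function(e) NA_real_)
  }
  n_dropped <- sum(is.na(stat))
  if (n_dropped > 0.01 * n_boot) {
    warn(paste0(
      n_dropped, " of ", n_boot,
      " bootstrap resamples had an undefined statistic and were dropped"
    ))
  }
  stat <- stat[!is.na(stat)]
  alpha <- 1 - ci_level
  ci <- unname(quantile(stat, c(alpha / 2, 1 - alpha / 2)))
  tibble(
    metric = metric, value = value,
    ci_low = ci[1], ci_high = ci[2],
    ci_level = ci_level, n_boot = as.integer(n_boot),
    n_dropped = as.integer(n_dropped), seed = as.integer(seed)
  )
}

#' Observer-permutation test for a group difference in an agreement metric
#'
#' The observed statistic is `metric(A) - metric(B)`. The null distribution
#' re-partitions the pooled observers at random into groups of the original
#' sizes and recomputes the difference; slices are never permuted, so the
#' within-slice correlation structure is preserved. The two-sided p-value is
#' `(1 + #{|delta*| >= |delta|}) / (1 + n_perm)`, so the smallest attainable
#' p is `1 / (n_perm + 1)`.
#'
#' @param labels_a,labels_b Label tables for the two disjoint observer
#'   groups, over the same slices in the same row order.
#' @param metric `"fleiss_kappa"` or `"pct_agreement"`.
#' @param n_perm Number of random re-partitions (default 10000).
#' @param seed Integer seed.
#' @param group_a,group_b Optional group names for the output.
#' @return A one-row tibble: `metric`, `group_a`, `group_b`, `delta`,
#'   `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(labels_a, labels_b,
                             metric = c("fleiss_kappa", "pct_agreement"),
                             n_perm = 10000L, seed,
                             group_a = "A", group_b = "B") {
  metric <- arg_match(metric)
  stopifnot(n_perm >= 1)
  ma <- as_label_matrix(labels_a)
  mb <- as_label_matrix(labels_b)
  if (nrow(ma) != nrow(mb)) abort("groups must rate the same slices")
  if (ncol(ma) < 2 || ncol(mb) < 2) {
    abort("each group needs at least 2 observers")
  }
  f <- metric_fun(metric)
  pooled <- cbind(ma, mb)
  na <- ncol(ma)
  delta <- f(ma) - f(mb)
  withr::local_seed(seed)
  hits <- 0L
  for (p in seq_len(n_perm)) {
    perm <- sample.int(ncol(pooled))
    da <- f(pooled[, perm[seq_len(na)], drop = FALSE])
    db <- f(pooled[, perm[-seq_len(na)], drop = FALSE])
    if (abs(da - db) >= abs(delta)) hits <- hits + 1L
  }
  tibble(
    metric = metric, group_a = group_a, group_b = group_b,
    delta = delta, p_value = (1 + hits) / (1 + n_perm),
    n_perm = as.integer(n_perm), seed = as.integer(seed)
  )
}

metric_fun <- function(metric) {
  switch(metric,
    fleiss_kappa = fleiss_kappa,
    pct_agreement = pct_agreement,
    cohen_kappa = function(m) {
      if (ncol(m) != 2) abort("cohen_kappa needs exactly 2 rating columns")
      cohen_kappa(m[, 1], m[, 2])
    }
  )
}

# Accept a logical matrix, or a data frame whose non-slice_id columns are
# logical ratings; returns items x raters logical matrix.
as_label_matrix <- function(labels) {
  if (is.matrix(labels)) {
    if (!is.logical(labels)) {
      if (!all(labels %in% c(0, 1))) abort("labels must be binary")
      labels <- labels == 1
    }
    return(labels)
  }
  if (is.data.frame(labels)) {
    df <- labels[setdiff(names(labels), "slice_id")]
    if (!all(vapply(df, is.logical, logical(1)))) {
      abort("label columns must be logical")
    }
    return(as.matrix(df))
  }
  abort("labels must be a matrix or data frame")
}
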