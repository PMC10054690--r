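#' ROC curve for one observer's ordinal confidence scores
#'
#' One operating point per distinct score value t used by the observer, with
#' the decision rule "call positive if score >= t", ordered by decreasing
#' threshold, plus the (0, 0) point (threshold above every score). Score 0
#' (no annotation) participates as the lowest ordinal level, so the lowest
#' threshold always yields (1, 1). The number of points therefore depends on
#' how many unique confidence levels the observer used.
#'
#' @param scores Numeric vector of per-slice scores (0 = not annotated,
#'   1..5 = confidence), one per slice.
#' @param truth Slice truth: a logical vector (`TRUE` = positive), or a
#'   character vector of "positive"/"negative".
#' @param observer_id Optional observer identifier stored on the curve.
#' @return An object of class `roc_curve`: a list with `points` (tibble of
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_thresholds` and `observer_id`.
#'   Use [tidy()] for the points and [glance()] for the scalar summary.
#' @export
#' @examples
#' roc_curve(c(5, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
roc_curve <- function(scores, truth, observer_id = NULL) {
  truth <- as_truth(truth)
  if (length(scores) != length(truth)) {
    abort("scores and truth must have equal length")
  }
  if (!any(truth) || all(truth)) {
    abort("reference must contain at least one positive and one negative slice")
  }
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  # cumulative counts down the sorted scores give all operating points at once
  ord <- order(scores, decreasing = TRUE)
  s_ord <- scores[ord]
  t_ord <- truth[ord]
  last_of_value <- which(!duplicated(s_ord, fromLast = TRUE))
  thresholds <- s_ord[last_of_value]
  tpr <- cumsum(t_ord)[last_of_value] / n_pos
  fpr <- cumsum(!t_ord)[last_of_value] / n_neg
  points <- tibble(
    threshold = c(Inf, thresholds),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
  new_roc_curve(points, observer_id = observer_id)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the curve from [roc_curve()]; algebraically equal
#' to the Mann-Whitney probability that a random positive slice outscores a
#' random negative one, with ties counted 1/2.
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, truth) {
  roc_curve(scores, truth)$auc
}

#' Diagonal average of several ROC curves
#'
#' Averages curves along lines perpendicular to the chance diagonal: for each
#' offset b in \[0, 2\] the line tpr = b - fpr crosses every monotone ROC
#' curve exactly once; the crossing points are averaged across curves and the
#' averaged vertices form the group curve. The offset grid is `n_grid`
#' equally spaced values in \[0, 2\] plus every input vertex's own offset, so
#' the average of piecewise-linear curves is computed exactly (in particular,
#' averaging copies of one curve returns that curve).
#'
#' @param curves A list of `roc_curve` objects.
#' @param n_grid Number of equally spaced offsets (default 201).
#' @return A `roc_curve` object (thresholds are `NA`; the `offset` column
#'   records each vertex's diagonal offset).
#' @export
diagonal_average <- function(curves, n_grid = 201L) {
  if (inherits(curves, "roc_curve")) curves <- list(curves)
  if (length(curves) == 0) abort("need at least one curve")
  if (!all(vapply(curves, inherits, logical(1), "roc_curve"))) {
    abort("curves must be roc_curve objects")
  }
  vertex_offsets <- unlist(lapply(curves, function(cv) {
    cv$points$fpr + cv$points$tpr
  }))
  offsets <- sort(unique(c(
    seq(0, 2, length.out = n_grid), vertex_offsets
  )))
  fpr_at <- vapply(curves, function(cv) {
    s <- cv$points$fpr + cv$points$tpr
    x <- cv$points$fpr
    keep <- !duplicated(s) # duplicate vertices share fpr by monotonicity
    stats::approx(s[keep], x[keep], xout = offsets, rule = 2)$y
  }, numeric(length(offsets)))
  fpr_mean <- rowMeans(as.matrix(fpr_at))
  points <- tibble(
    threshold = NA_real_,
    fpr = fpr_mean,
    tpr = offsets - fpr_mean,
    offset = offsets
  )
  new_roc_curve(points, observer_id = NULL)
}

#' Operating point of an ROC curve at a target sensitivity
#'
#' Returns the curve vertex with the smallest sensitivity at or above the
#' target; with `interpolate = TRUE` the point is interpolated linearly along
#' the curve so its sensitivity equals the target exactly.
#'
#' @param curve A `roc_curve` object.
#' @param target_sensitivity Target sensitivity in \[0, 1\].
#' @param interpolate Interpolate along the curve instead of returning a
#'   vertex.
#' @return A one-row tibble with `sensitivity` and `specificity`.
#' @export
operating_point <- function(curve, target_sensitivity, interpolate = FALSE) {
  stopifnot(inherits(curve, "roc_curve"))
  if (target_sensitivity < 0 || target_sensitivity > 1) {
    abort("target_sensitivity must be in [0, 1]")
  }
  pts <- curve$points
  if (interpolate) {
    keep <- !duplicated(pts$tpr)
    fpr <- stats::approx(pts$tpr[keep], pts$fpr[keep],
                         xout = target_sensitivity, rule = 2)$y
    return(tibble(sensitivity = target_sensitivity, specificity = 1 - fpr))
  }
  ok <- which(pts$tpr >= target_sensitivity)
  i <- ok[which.min(pts$tpr[ok])]
  tibble(sensitivity = pts$tpr[i], specificity = 1 - pts$fpr[i])
}

#' Diagonally averaged group AUC with a two-way bootstrap interval
#'
#' The group summary is the AUC of the diagonal average of the group members'
#' ROC curves. The confidence interval resamples readers and cases jointly:
#' each bootstrap draw resamples the group's observers with replacement and
#' the slices with replacement within the positive and negative reference
#' strata (so every resample keeps both classes), then recomputes the
#' diagonally averaged AUC.
#'
#' @param scores A slice-by-observer score table (the group's observers only),
#'   as from [slice_scores()]; a `slice_id` column is ignored for computation
#'   but, when present, rows are aligned to `reference` by slice id.
#' @param reference Reference standard tibble (see [read_reference()]) or a
#'   logical/character truth vector aligned to the rows of `scores`.
#' @param n_boot Number of bootstrap draws (default 2000).
#' @param ci_level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @param group Optional group name for the output.
#' @return A one-row tibble: `group`, `mean_auc`, `ci_low`, `ci_high`,
#'   `n_boot`, `seed`.
#' @export
group_auc_summary <- function(scores, reference, n_boot = 2000L,
                              ci_level = 0.95, seed, group = NA_character_) {
  sm <- as_score_matrix(scores, reference)
  if (ncol(sm$scores) < 2) abort("group must have at least 2 observers")
  mean_auc <- group_mean_auc(sm$scores, sm$truth)
  withr::local_seed(seed)
  boots <- replicate(n_boot, {
    rs <- resample_two_way(sm$scores, sm$truth)
    group_mean_auc(rs$scores, rs$truth)
  })
  alpha <- 1 - ci_level
  ci <- unname(quantile(boots, c(alpha / 2, 1 - alpha / 2)))
  tibble(
    group = group, mean_auc = mean_auc,
    ci_low = ci[1], ci_high = ci[2],
    n_boot = as.integer(n_boot), seed = as.integer(seed)
  )
}

#' Compare two reader groups' diagonally averaged AUCs
#'
#' The difference in diagonally averaged AUC is tested with a z statistic
#' whose standard error comes from a two-way bootstrap of the difference:
#' each draw resamples slices once (shared by both groups, within reference
#' strata) and each group's observers independently. Two-sided normal
#' p-value.
#'
#' @param scores_a,scores_b Score tables for the two observer groups, over
#'   the same slices.
#' @inheritParams group_auc_summary
#' @param group_a,group_b Optional group names.
#' @return A one-row tibble: `group_a`, `group_b`, `auc_a`, `auc_b`, `delta`,
#'   `z`, `p_value`, `n_boot`, `seed`.
#' @export
compare_group_auc <- function(scores_a, scores_b, reference, n_boot = 2000L,
                              seed, group_a = "A", group_b = "B") {
  sa <- as_score_matrix(scores_a, reference)
  sb <- as_score_matrix(scores_b, reference)
  if (!identical(sa$truth, sb$truth)) {
    abort("both groups must rate the same slices")
  }
  if (ncol(sa$scores) < 2 || ncol(sb$scores) < 2) {
    abort("each group needs at least 2 observers")
  }
  auc_a <- group_mean_auc(sa$scores, sa$truth)
  auc_b <- group_mean_auc(sb$scores, sb$truth)
  delta <- auc_a - auc_b
  withr::local_seed(seed)
  pos <- which(sa$truth)
  neg <- which(!sa$truth)
  deltas <- replicate(n_boot, {
    rows <- c(sample(pos, length(pos), replace = TRUE),
              sample(neg, length(neg), replace = TRUE))
    truth_b <- sa$truth[rows]
    ca <- sample.int(ncol(sa$scores), ncol(sa$scores), replace = TRUE)
    cb <- sample.int(ncol(sb$scores), ncol(sb$scores), replace = TRUE)
    group_mean_auc(sa$scores[rows, ca, drop = FALSE], truth_b) -
      group_mean_auc(sb$scores[rows, cb, drop = FALSE], truth_b)
  })
  se <- sd(deltas)
  z <- if (se == 0) 0 else delta / se
  tibble(
    group_a = group_a, group_b = group_b,
    auc_a = auc_a, auc_b = auc_b, delta = delta,
    z = z, p_value = 2 * pnorm(-abs(z)),
    n_boot = as.integer(n_boot), seed = as.integer(seed)
  )
}

# ---- internals --------------------------------------------------------------

new_roc_curve <- function(points, observer_id = NULL) {
  stopifnot(all(diff(points$fpr) >= -1e-12), all(diff(points$tpr) >= -1e-12))
  structure(
    list(
      points = points,
      auc = trapezoid(points$fpr, points$tpr),
      n_thresholds = nrow(points),
      observer_id = observer_id
    ),
    class = "roc_curve"
  )
}

trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

as_truth <- function(truth) {
  if (is.character(truth) || is.factor(truth)) {
    truth <- as.character(truth)
    if (!all(truth %in% c("positive", "negative"))) {
      abort("truth labels must be 'positive' or 'negative'")
    }
    return(truth == "positive")
  }
  if (is.logical(truth)) return(truth)
  if (is.numeric(truth) && all(truth %in% c(0, 1))) return(truth == 1)
  abort("truth must be logical, 0/1, or 'positive'/'negative'")
}

# Normalise a score table + reference into an aligned numeric matrix and
# logical truth vector.
as_score_matrix <- function(scores, reference) {
  if (is.data.frame(scores) && "slice_id" %in% names(scores) &&
      is.data.frame(reference)) {
    reference <- validate_reference(reference)
    idx <- match(scores$slice_id, reference$slice_id)
    if (anyNA(idx)) abort("score table has slices missing from the reference")
    truth <- reference$label[idx] == "positive"
    m <- as.matrix(scores[setdiff(names(scores), "slice_id")])
  } else {
    truth <- as_truth(reference)
    m <- if (is.data.frame(scores)) {
      as.matrix(scores[setdiff(names(scores), "slice_id")])
    } else {
      as.matrix(scores)
    }
  }
  if (nrow(m) != length(truth)) abort("scores and reference sizes differ")
  if (!any(truth) || all(truth)) {
    abort("reference must contain both classes")
  }
  list(scores = m, truth = truth)
}

# AUC of the diagonal average of the per-column ROC curves of a score matrix.
# Matrix-only hot path used inside bootstrap loops; agrees with the
# roc_curve() + diagonal_average() composition (asserted in tests).
group_mean_auc <- function(score_mat, truth, n_grid = 201L) {
  n_pos <- sum(truth)
  n_neg <- length(truth) - n_pos
  verts <- lapply(seq_len(ncol(score_mat)), function(j) {
    scores <- score_mat[, j]
    ord <- order(scores, decreasing = TRUE)
    s_ord <- scores[ord]
    t_ord <- truth[ord]
    last <- which(!duplicated(s_ord, fromLast = TRUE))
    cbind(
      fpr = c(0, cumsum(!t_ord)[last] / n_neg),
      tpr = c(0, cumsum(t_ord)[last] / n_pos)
    )
  })
  offsets <- sort(unique(c(
    seq(0, 2, length.out = n_grid),
    unlist(lapply(verts, function(v) v[, 1] + v[, 2]))
  )))
  fpr_sum <- numeric(length(offsets))
  for (v in verts) {
    s <- v[, 1] + v[, 2]
    keep <- !duplicated(s)
    fpr_sum <- fpr_sum +
      stats::approx(s[keep], v[keep, 1], xout = offsets, rule = 2)$y
  }
  fpr_mean <- fpr_sum / length(verts)
  tpr_mean <- offsets - fpr_mean
  trapezoid(fpr_mean, tpr_mean)
}

resample_two_way <- function(score_mat, truth) {
  pos <- which(truth)
  neg <- which(!truth)
  rows <- c(sample(pos, length(pos), replace = TRUE),
            sample(neg, length(neg), replace = TRUE))
  cols <- sample.int(ncol(score_mat), ncol(score_mat), replace = TRUE)
  list(scores = score_mat[rows, cols, drop = FALSE], truth = truth[rows])
}

#' @export
print.roc_curve <- function(x, ...) {
  id <- if (is.null(x$observer_id)) "" else paste0(" [", x$observer_id, "]")
  cat(sprintf("<roc_curve%s: %d points, AUC = %.3f>\n",
              id, nrow(x$points), x$auc))
  invisible(x)
}

#' @export
tidy.roc_curve <- function(x, ...) {
  pts <- x$points
  if (!is.null(x$observer_id)) {
    pts <- mutate(pts, observer_id = x$observer_id, .before = 1)
  }
  pts
}

#' @export
glance.roc_curve <- function(x, ...) {
  tibble(
    auc = x$auc,
    n_thresholds = x$n_thresholds,
    observer_id = x$observer_id %||% NA_character_
  )
}

#' Plot an ROC curve
#'
#' @param object A `roc_curve` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("%sAUC = %.3f",
                      if (is.null(object$observer_id)) "" else
                        paste0(object$observer_id, ": "),
                      object$auc)
    ) +
    ggplot2::theme_minimal()
}
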