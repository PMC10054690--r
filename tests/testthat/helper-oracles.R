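# Independent brute-force oracles, written from the textbook formulas with
# explicit loops over categories/pairs so they share no code path with the
# package implementations.

oracle_fleiss <- function(m) {
  stopifnot(is.logical(m))
  N <- nrow(m)
  n <- ncol(m)
  categories <- c(FALSE, TRUE)
  # n_ij: raters assigning category j to item i
  nij <- matrix(0, N, length(categories))
  for (i in seq_len(N)) {
    for (j in seq_along(categories)) {
      nij[i, j] <- sum(m[i, ] == categories[j])
    }
  }
  P_i <- numeric(N)
  for (i in seq_len(N)) {
    P_i[i] <- (sum(nij[i, ]^2) - n) / (n * (n - 1))
  }
  p_j <- colSums(nij) / (N * n)
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  (P_bar - P_e) / (1 - P_e)
}

oracle_cohen <- function(a, b) {
  tab <- matrix(0, 2, 2)
  for (i in seq_along(a)) {
    tab[a[i] + 1, b[i] + 1] <- tab[a[i] + 1, b[i] + 1] + 1
  }
  tab <- tab / length(a)
  p_o <- tab[1, 1] + tab[2, 2]
  p_e <- sum(rowSums(tab) * colSums(tab))
  (p_o - p_e) / (1 - p_e)
}

# Mann-Whitney pairwise count with ties worth 1/2.
oracle_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Analytic diagonal average of a list of curves given as vertex matrices:
# for each offset b, intersect each piecewise-linear curve with
# tpr = b - fpr by root-finding on the vertex sums, average the points,
# integrate with the trapezoid rule on a fine offset grid.
oracle_diagonal_average_auc <- function(vertex_list, offsets) {
  intersect_at <- function(v, b) {
    s <- v[, 1] + v[, 2]
    i <- max(which(s <= b + 1e-12))
    if (i == nrow(v)) return(v[i, ])
    w <- (b - s[i]) / (s[i + 1] - s[i])
    v[i, ] + w * (v[i + 1, ] - v[i, ])
  }
  pts <- t(vapply(
    offsets,
    function(b) {
      xs <- vapply(vertex_list, function(v) intersect_at(v, b), numeric(2))
      rowMeans(xs)
    },
    numeric(2)
  ))
  sum(diff(pts[, 1]) * (utils::head(pts[, 2], -1) + utils::tail(pts[, 2], -1)) / 2)
}
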