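test_that("ROC curves have the documented shape and endpoints", {
  # perfect separation
  cv <- roc_curve(c(5, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cv$auc, 1)
  expect_true(any(cv$points$fpr == 0 & cv$points$tpr == 1))

  # uninformative reader: every slice scored identically
  cv <- roc_curve(rep(3, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(cv$points$fpr, c(0, 1))
  expect_equal(cv$points$tpr, c(0, 1))
  expect_equal(cv$auc, 0.5)

  # 3 distinct confidence levels -> 3 threshold points plus the (0,0) origin;
  # the lowest threshold is the (1,1) endpoint
  cv <- roc_curve(c(0, 2, 2, 5, 5, 0), c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(cv$n_thresholds, 4)
  expect_equal(cv$points$fpr[1], 0)
  expect_equal(cv$points$tpr[1], 0)
  expect_equal(utils::tail(cv$points$fpr, 1), 1)
  expect_equal(utils::tail(cv$points$tpr, 1), 1)
  expect_true(all(diff(cv$points$fpr) >= 0))
  expect_true(all(diff(cv$points$tpr) >= 0))

  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "negative")
})

test_that("trapezoidal AUC equals the tie-corrected pairwise count", {
  expect_equal(auc(c(4, 2, 3, 1), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auc(c(3, 3), c(TRUE, FALSE)), 0.5)
  withr::with_seed(31, {
    for (i in 1:50) {
      n <- sample(10:40, 1)
      truth <- c(TRUE, FALSE, stats::runif(n - 2) < 0.4)
      scores <- sample(0:5, n, replace = TRUE)
      expect_equal(auc(scores, truth), oracle_auc(scores, truth),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with pROC on ordinal and continuous scores", {
  skip_if_not_installed("pROC")
  withr::with_seed(17, {
    truth <- stats::runif(50) < 0.4
    truth[1:2] <- c(TRUE, FALSE)
    ordinal <- sample(0:5, 50, replace = TRUE)
    continuous <- stats::rnorm(50) + truth
    for (s in list(ordinal, continuous)) {
      expect_equal(
        auc(s, truth),
        as.numeric(pROC::auc(pROC::roc(truth, s, quiet = TRUE,
                                       direction = "<"))),
        tolerance = 1e-12
      )
    }
  })
})

test_that("AUC is invariant to monotone score transforms and flips with labels", {
  withr::with_seed(5, {
    scores <- sample(0:5, 30, replace = TRUE)
    truth <- c(TRUE, FALSE, stats::runif(28) < 0.4)
    a <- auc(scores, truth)
    expect_equal(auc(exp(scores), truth), a)
    expect_equal(auc(2 * scores + 7, truth), a)
    expect_equal(auc(scores, !truth), 1 - a)
  })
})

test_that("diagonal averaging is exact on copies and preserves endpoints", {
  cv <- roc_curve(c(0, 2, 2, 5, 3, 0, 1), c(FALSE, FALSE, TRUE, TRUE, TRUE,
                                            FALSE, FALSE))
  avg <- diagonal_average(list(cv, cv, cv))
  expect_equal(avg$auc, cv$auc, tolerance = 1e-9)
  # every original vertex is reproduced exactly
  for (i in seq_len(nrow(cv$points))) {
    b <- cv$points$fpr[i] + cv$points$tpr[i]
    j <- which.min(abs(avg$points$offset - b))
    expect_equal(avg$points$fpr[j], cv$points$fpr[i], tolerance = 1e-9)
  }
  expect_equal(avg$points$fpr[1], 0)
  expect_equal(avg$points$tpr[1], 0)
  expect_equal(utils::tail(avg$points$fpr, 1), 1)
  expect_equal(utils::tail(avg$points$tpr, 1), 1)
})

test_that("diagonal average of dominating curves stays between their AUCs", {
  withr::with_seed(11, {
    truth <- c(TRUE, FALSE, stats::runif(40) < 19 / 61)
    curves <- lapply(c(0.8, 1.5, 2.5), function(d) {
      scores <- pmin(5, pmax(0, round(d * truth + stats::rnorm(42) + 2)))
      roc_curve(scores, truth)
    })
    aucs <- vapply(curves, function(cv) cv$auc, numeric(1))
    avg <- diagonal_average(curves)
    expect_gte(avg$auc, min(aucs) - 1e-9)
    expect_lte(avg$auc, max(aucs) + 1e-9)
  })
})

test_that("operating points: vertex lookup and interpolation", {
  chance <- diagonal_average(list(
    roc_curve(rep(1, 4), c(TRUE, FALSE, TRUE, FALSE))
  ))
  op <- operating_point(chance, 0.93, interpolate = TRUE)
  expect_equal(op$sensitivity, 0.93)
  expect_equal(op$specificity, 0.07, tolerance = 1e-9)

  perfect <- roc_curve(c(5, 5, 1, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(operating_point(perfect, 0.4)$specificity, 1)
  expect_equal(operating_point(perfect, 1)$specificity, 1)

  toy <- structure(
    list(points = tibble::tibble(threshold = c(Inf, 2, 1),
                                 fpr = c(0, 0.2, 1), tpr = c(0, 0.6, 1)),
         auc = NA_real_, n_thresholds = 3L, observer_id = NULL),
    class = "roc_curve"
  )
  op <- operating_point(toy, 0.6)
  expect_equal(op$sensitivity, 0.6)
  expect_equal(op$specificity, 0.8)
})

test_that("group AUC summary is seeded and degenerate for identical perfect readers", {
  truth <- rep(c(TRUE, FALSE), c(5, 10))
  scores <- matrix(rep(ifelse(truth, 5, 1), 3), ncol = 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  gs <- group_auc_summary(scores, truth, n_boot = 50, seed = 2)
  expect_equal(gs$mean_auc, 1)
  expect_equal(gs$ci_low, 1)
  expect_equal(gs$ci_high, 1)

  st <- simulate_benchmark_study(3)
  sc <- slice_scores(st$annotations, st$reference$slice_id,
                     st$profiles$observer_id, 1L)
  g1 <- group_auc_summary(sc[1:6], st$reference, n_boot = 100, seed = 7,
                          group = "g")
  g2 <- group_auc_summary(sc[1:6], st$reference, n_boot = 100, seed = 7,
                          group = "g")
  expect_identical(g1, g2)
  expect_lte(g1$ci_low, g1$mean_auc)
  expect_gte(g1$ci_high, g1$mean_auc)
})

test_that("group AUC comparison: self-comparison is null, seeded", {
  st <- simulate_benchmark_study(4)
  sc <- slice_scores(st$annotations, st$reference$slice_id,
                     st$profiles$observer_id, 1L)
  grp <- sc[c("slice_id", "obs04", "obs05", "obs06")]
  res <- compare_group_auc(grp, grp, st$reference, n_boot = 100, seed = 5)
  expect_equal(res$delta, 0)
  expect_equal(res$p_value, 1)
  expect_identical(
    res,
    compare_group_auc(grp, grp, st$reference, n_boot = 100, seed = 5)
  )
})

test_that("the bootstrap group-AUC summary matches the explicit curve composition", {
  st <- simulate_benchmark_study(9)
  sc <- slice_scores(st$annotations, st$reference$slice_id,
                     st$profiles$observer_id, 1L)
  truth <- st$reference$label == "positive"
  for (cols in list(4:8, c(5, 9, 12), 10:15)) {
    m <- as.matrix(sc[st$profiles$observer_id[cols]])
    curves <- lapply(seq_len(ncol(m)), function(j) roc_curve(m[, j], truth))
    expect_equal(group_mean_auc(m, truth), diagonal_average(curves)$auc,
                 tolerance = 1e-12)
  }
})

test_that("group AUC z-test does not reject above the nominal level under the null", {
  # The two-way (reader x case) bootstrap double-counts the reader-by-case
  # interaction with exchangeable readers, so the z-test errs on the
  # conservative side; validity (type I <= nominal, up to Monte-Carlo error
  # at 200 replicates) is what is asserted.
  obs <- sim_observers(6, d = 1.2)
  rejections <- withr::with_seed(99, {
    sum(replicate(200, {
      st <- simulate_study(sim_config(obs, n_patients = 10,
                                      seed = sample.int(1e6, 1)))
      sc <- slice_scores(st$annotations, st$reference$slice_id,
                         obs$observer_id, 1L)
      res <- compare_group_auc(sc[1:4], sc[c(1, 5:7)], st$reference,
                               n_boot = 150, seed = sample.int(1e6, 1))
      res$p_value < 0.05
    }))
  })
  expect_lte(rejections / 200, 0.09)
})
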