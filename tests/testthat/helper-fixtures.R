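# In-code fixtures shared across test files.

fixture_annotations <- function() {
  tibble::tibble(
    observer_id = c("obsA", "obsA", "obsA", "obsB", "obsB"),
    patient_id = c("pat1", "pat1", "pat2", "pat1", "pat2"),
    slice_id = c("sl1", "sl1", "sl3", "sl2", "sl3"),
    x_min = c(10L, 50L, 5L, 0L, 30L),
    y_min = c(10L, 60L, 5L, 0L, 40L),
    x_max = c(30L, 90L, 25L, 20L, 60L),
    y_max = c(30L, 80L, 25L, 15L, 70L),
    confidence = c(2L, 4L, 3L, 5L, 1L),
    session = c(1L, 1L, 1L, 1L, 2L)
  )
}

fixture_observers <- function() {
  tibble::tibble(
    observer_id = c("obsA", "obsB"),
    years_experience = c(2L, 10L),
    cine_cases = c(0L, 100L),
    adhesion_cases = c(0L, 50L),
    clinical_threshold_pct = c(40L, 60L),
    is_consensus = c(FALSE, FALSE)
  )
}

fixture_reference <- function() {
  tibble::tibble(
    slice_id = c("sl1", "sl2", "sl3"),
    patient_id = c("pat1", "pat1", "pat2"),
    label = c("positive", "negative", "positive")
  )
}

random_annotations <- function(n, seed) {
  withr::with_seed(seed, {
    x_min <- sample(0:200, n, replace = TRUE)
    y_min <- sample(0:150, n, replace = TRUE)
    slice <- sample(sprintf("sl%02d", 1:10), n, replace = TRUE)
    tibble::tibble(
      observer_id = sample(sprintf("obs%02d", 1:5), n, replace = TRUE),
      patient_id = paste0("pat", substr(slice, 3, 3)),
      slice_id = slice,
      x_min = x_min,
      y_min = y_min,
      x_max = x_min + sample(1:50, n, replace = TRUE),
      y_max = y_min + sample(1:40, n, replace = TRUE),
      confidence = sample(1:5, n, replace = TRUE),
      session = sample(1:2, n, replace = TRUE)
    )
  })
}

random_label_matrix <- function(n_items, n_raters, seed, p = 0.5) {
  withr::with_seed(seed, {
    repeat {
      m <- matrix(stats::runif(n_items * n_raters) < p, n_items, n_raters,
                  dimnames = list(NULL, paste0("r", seq_len(n_raters))))
      if (any(m) && !all(m)) return(m)
    }
  })
}
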