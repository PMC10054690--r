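test_that("simulated studies are deterministic and structurally consistent", {
  st1 <- simulate_benchmark_study(11)
  st2 <- simulate_benchmark_study(11)
  expect_identical(st1$annotations, st2$annotations)
  expect_identical(st1$reference, st2$reference)

  # canonical design facts
  expect_equal(nrow(st1$reference), 61)
  expect_equal(sum(st1$reference$label == "positive"), 19)
  expect_equal(length(unique(st1$reference$patient_id)), 10)
  expect_equal(nrow(st1$profiles), 15)
  expect_equal(sum(st1$profiles$is_consensus), 3)
  pl <- patient_labels(st1$reference)
  expect_equal(sum(pl$label == "negative"), 3)

  # written files are byte-identical across runs with the same seed
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(st1, d1)
  write_study(st2, d2)
  for (f in c("annotations.csv", "observers.csv", "reference.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # annotations are valid records for the I/O layer
  expect_silent(validate_annotations(st1$annotations))
})

test_that("patient labels are the OR of slice truths by construction", {
  st <- simulate_study(sim_config(sim_observers(3), n_patients = 12,
                                  seed = 21))
  pl <- patient_labels(st$reference)
  by_hand <- tapply(st$reference$label == "positive",
                    st$reference$patient_id, any)
  expect_equal(pl$label == "positive",
               as.vector(by_hand[pl$patient_id]), ignore_attr = TRUE)
})

test_that("theoretical AUC follows the closed form and its inverse", {
  expect_equal(theoretical_auc(0), 0.5)
  expect_equal(theoretical_auc(1e6), 1)
  expect_equal(theoretical_auc(1.81), pnorm(1.81 / sqrt(2)), tolerance = 1e-12)
  expect_equal(round(theoretical_auc(1.81), 3), 0.9)
  expect_equal(theoretical_auc(1.81, sigma_c = 1),
               pnorm(1.81 / sqrt(4)), tolerance = 1e-12)
  for (target in c(0.6, 0.72, 0.9)) {
    expect_equal(theoretical_auc(discrimination_for_auc(target, 0.5), 0.5),
                 target, tolerance = 1e-12)
  }
})

test_that("no signal means chance-level AUC; strong signal means near-perfect", {
  cfg <- sim_config(sim_observers(2, d = 0), n_patients = 1000,
                    slices_per_patient = 5L, case_effect_sd = 0, seed = 13)
  st <- simulate_study(cfg)
  truth <- st$reference$label == "positive"
  lat <- st$latent[st$latent$observer_id == "obs01", ]
  expect_equal(auc(lat$latent, truth), 0.5, tolerance = 0.03)

  cfg <- sim_config(sim_observers(3, d = 10, clinical_threshold_pct = 100L),
                    n_patients = 100,
                    slices_per_patient = 5L, case_effect_sd = 0, seed = 14)
  st <- simulate_study(cfg)
  truth <- st$reference$label == "positive"
  sc <- slice_scores(st$annotations, st$reference$slice_id,
                     sprintf("obs%02d", 1:3), 1L)
  expect_gt(auc(sc$obs01, truth), 0.98)
  lab <- binarize_scores(sc, st$profiles)
  expect_gt(fleiss_kappa(lab), 0.95)
})

test_that("expected AUC and group kappa increase with discrimination", {
  auc_at <- function(d) {
    st <- simulate_study(sim_config(sim_observers(4, d = d),
                                    n_patients = 400, slices_per_patient = 5L,
                                    seed = 17))
    truth <- st$reference$label == "positive"
    sc <- slice_scores(st$annotations, st$reference$slice_id,
                       sprintf("obs%02d", 1:4), 1L)
    lab <- binarize_scores(sc, st$profiles)
    c(auc = mean(sapply(sprintf("obs%02d", 1:4),
                        function(o) auc(sc[[o]], truth))),
      kappa = fleiss_kappa(lab))
  }
  grid <- sapply(c(0.3, 1, 2.5), auc_at)
  expect_true(all(diff(grid["auc", ]) > 0))
  expect_true(all(diff(grid["kappa", ]) > 0))
})

test_that("session agreement rises as intra-session noise falls, exact at zero", {
  kappa_at <- function(tau) {
    st <- simulate_study(sim_config(
      sim_observers(2, d = 1.2, n_sessions = 2L), n_patients = 300,
      slices_per_patient = 5L, intra_session_noise = tau, seed = 23
    ))
    ann1 <- st$annotations[st$annotations$observer_id == "obs01", ]
    s1 <- slice_scores(ann1, st$reference$slice_id, "obs01", 1L)
    s2 <- slice_scores(ann1, st$reference$slice_id, "obs01", 2L)
    lab1 <- binarize_scores(s1, st$profiles)$obs01
    lab2 <- binarize_scores(s2, st$profiles)$obs01
    cohen_kappa(lab1, lab2)
  }
  k <- sapply(c(0, 0.8, 2.5), kappa_at)
  expect_equal(k[1], 1)
  expect_true(all(diff(k) < 0))
})

test_that("empirical continuous-score AUC matches the closed form", {
  d <- discrimination_for_auc(0.85, sigma_c = 1)
  st <- simulate_study(sim_config(sim_observers(1, d = d), n_patients = 1200,
                                  slices_per_patient = 5L, case_effect_sd = 1,
                                  seed = 29))
  truth <- st$reference$label == "positive"
  expect_equal(auc(st$latent$latent, truth), 0.85, tolerance = 0.02)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(sim_observers(2), slice_prevalence = 1.5), "prevalence")
  expect_error(sim_config(sim_observers(2), cutpoints = c(1, 2, 3, 4)), "cutpoints")
  expect_error(sim_config(sim_observers(2), cutpoints = c(1, 1, 2, 3, 4)), "cutpoints")
  bad <- sim_observers(2)
  bad$d <- -1
  expect_error(sim_config(bad), "d must be")
  expect_error(sim_config(sim_observers(2), case_effect_sd = -1), "case_effect_sd")
  expect_error(
    sim_config(sim_observers(2), n_negative_patients = 3),
    "n_positive_slices"
  )
})
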