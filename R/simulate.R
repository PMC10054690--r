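#' Configuration for a synthetic multi-reader study
#'
#' The generator uses an equal-variance binormal latent model with a shared
#' case random effect. Slice truth D is Bernoulli(`slice_prevalence`); each
#' slice carries a case effect eta ~ N(0, `case_effect_sd`^2) shared by all
#' readers, inducing inter-reader correlation beyond the truth itself.
#' Reader r in session s sees the latent signal
#'
#'   x = d_r * D + lambda_r * eta + (u + tau * v_s) / sqrt(1 + tau^2),
#'
#' where u ~ N(0,1) is a reader-slice effect shared across sessions, v_s is
#' session-specific noise and tau = `intra_session_noise`; at tau = 0 the two
#' sessions see the same draw, so test-retest agreement is perfect. The
#' reader's loading lambda_r on the case effect (`case_loading`, default 1)
#' controls how much of the panel's shared perception the reader picks up:
#' readers with a common training background agree with each other beyond
#' what the truth induces. The session-noise construction keeps the marginal
#' noise variance of u and v at 1 for any tau, so a reader's continuous-score
#' AUC is `theoretical_auc(d_r, lambda_r * case_effect_sd)` regardless of
#' tau. The latent signal is cut at `cutpoints` into the ordinal score 0..5;
#' every score >= 1 emits one bounding-box annotation (the box location is
#' cosmetic and random: downstream analysis is slice-level).
#'
#' @param observers A tibble with one row per reader: the profile columns of
#'   [read_observers()] plus `d` (discrimination, standardized mean shift for
#'   positive slices, >= 0), `n_sessions` (1 or 2) and optionally
#'   `case_loading` (lambda, >= 0, default 1). See [sim_observers()] for a
#'   quick homogeneous panel.
#' @param n_patients Number of patients (default 10).
#' @param slices_per_patient Either a set of allowed per-patient slice counts
#'   to sample from (default 5:7) or an exact vector of length `n_patients`.
#' @param slice_prevalence Probability a slice is truly positive (default
#'   19/61, the prevalence of the motivating study).
#' @param n_positive_slices Optional exact number of positive slices; when
#'   set, positives are placed by sampling instead of Bernoulli draws.
#' @param n_negative_patients Optional exact number of all-negative patients
#'   (requires `n_positive_slices`); every remaining patient gets at least
#'   one positive slice.
#' @param cutpoints Five strictly increasing cut values binning the latent
#'   signal into scores 0..5. The defaults place the first cut at the 60th
#'   percentile of the marginal latent signal of an experienced reader
#'   (d = 1.65, lambda = 1.4, `case_effect_sd` = 1, prevalence 19/61) and the
#'   rest at the 72nd, 82nd, 90th and 96th percentiles, so readers annotate
#'   a realistic minority of slices and use the upper confidence levels
#'   progressively more sparingly.
#' @param case_effect_sd Standard deviation of the shared case effect
#'   (default 1).
#' @param intra_session_noise Session-specific noise mixing weight tau >= 0
#'   (default 1.2, giving a between-session noise correlation of
#'   1 / (1 + tau^2) = 0.41).
#' @param seed Integer seed; the whole study is a deterministic function of
#'   the configuration.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(observers,
                       n_patients = 10L,
                       slices_per_patient = 5:7,
                       slice_prevalence = 19 / 61,
                       n_positive_slices = NULL,
                       n_negative_patients = NULL,
                       cutpoints = c(0.97, 1.6, 2.24, 2.94, 3.85),
                       case_effect_sd = 1,
                       intra_session_noise = 1.2,
                       seed = 1L) {
  observers <- as_tibble(observers)
  needed <- c(
    "observer_id", "years_experience", "cine_cases", "adhesion_cases",
    "clinical_threshold_pct", "is_consensus", "d", "n_sessions"
  )
  check_columns(observers, needed, "observer specs")
  if (!"case_loading" %in% names(observers)) observers$case_loading <- 1
  if (any(observers$case_loading < 0)) abort("case_loading must be >= 0")
  if (any(observers$d < 0)) abort("discrimination d must be >= 0")
  if (!all(observers$n_sessions %in% 1:2)) abort("n_sessions must be 1 or 2")
  if (!(slice_prevalence > 0 && slice_prevalence < 1)) {
    abort("slice_prevalence must be in (0, 1)")
  }
  if (length(cutpoints) != 5 || any(diff(cutpoints) <= 0)) {
    abort("cutpoints must be 5 strictly increasing values")
  }
  if (case_effect_sd < 0) abort("case_effect_sd must be >= 0")
  if (intra_session_noise < 0) abort("intra_session_noise must be >= 0")
  if (n_patients < 1) abort("need at least one patient")
  if (!is.null(n_negative_patients) && is.null(n_positive_slices)) {
    abort("n_negative_patients requires n_positive_slices")
  }
  structure(
    list(
      observers = observers,
      n_patients = as.integer(n_patients),
      slices_per_patient = as.integer(slices_per_patient),
      slice_prevalence = slice_prevalence,
      n_positive_slices = n_positive_slices,
      n_negative_patients = n_negative_patients,
      cutpoints = cutpoints,
      case_effect_sd = case_effect_sd,
      intra_session_noise = intra_session_noise,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Quick homogeneous observer panel for simulations
#'
#' @param n Number of readers.
#' @param d Discrimination, recycled over readers.
#' @param clinical_threshold_pct Clinical-significance threshold in percent,
#'   recycled.
#' @param n_sessions 1 or 2, recycled.
#' @return An observer-spec tibble for [sim_config()].
#' @export
sim_observers <- function(n, d = 1, clinical_threshold_pct = 40L,
                          n_sessions = 1L) {
  tibble(
    observer_id = sprintf("obs%02d", seq_len(n)),
    years_experience = 5L,
    cine_cases = 30L,
    adhesion_cases = 2L,
    clinical_threshold_pct = as.integer(
      rep_len(clinical_threshold_pct, n)
    ),
    is_consensus = FALSE,
    d = rep_len(d, n),
    n_sessions = as.integer(rep_len(n_sessions, n))
  )
}

#' Simulate a multi-reader annotation study
#'
#' Draws a complete synthetic study from the latent model described in
#' [sim_config()]: a slice-level reference standard grouped into patients,
#' per-reader per-session ordinal scores, and one bounding-box annotation per
#' scored slice, in the same tabular dialect the I/O functions read and
#' write.
#'
#' @param config A `sim_config` object.
#' @return A `simulated_study` object: a list with `annotations`, `profiles`,
#'   `reference`, `latent` (slice x observer x session continuous signals and
#'   scores, for validation against [theoretical_auc()]) and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  obs <- config$observers

  # slices and patients
  spp <- config$slices_per_patient
  counts <- if (length(spp) == config$n_patients && config$n_patients > 1) {
    spp
  } else if (length(spp) == 1L) {
    rep(spp, config$n_patients)
  } else {
    sample(spp, config$n_patients, replace = TRUE)
  }
  n_slices <- sum(counts)
  patient_id <- rep(sprintf("pat%03d", seq_len(config$n_patients)), counts)
  slice_id <- sprintf("sl%03d", seq_len(n_slices))

  truth <- draw_truth(config, counts, patient_id, n_slices)
  eta <- rnorm(n_slices, 0, config$case_effect_sd)
  tau <- config$intra_session_noise

  latent <- vector("list", nrow(obs) * 2L)
  k <- 0L
  for (j in seq_len(nrow(obs))) {
    u <- rnorm(n_slices)
    for (s in seq_len(obs$n_sessions[j])) {
      v <- rnorm(n_slices)
      eps <- (u + tau * v) / sqrt(1 + tau^2)
      x <- obs$d[j] * truth + obs$case_loading[j] * eta + eps
      score <- findInterval(x, config$cutpoints)
      k <- k + 1L
      latent[[k]] <- tibble(
        slice_id = slice_id,
        patient_id = patient_id,
        observer_id = obs$observer_id[j],
        session = as.integer(s),
        latent = x,
        score = as.integer(score)
      )
    }
  }
  latent <- bind_rows(latent[seq_len(k)])

  ann <- filter(latent, .data$score >= 1L)
  # cosmetic fixed-size boxes at random valid positions (192 x 256 frames)
  box <- 24L
  ann <- ann %>%
    mutate(
      x_min = as.integer(floor(runif(n(), 0, 256 - box))),
      y_min = as.integer(floor(runif(n(), 0, 192 - box))),
      x_max = .data$x_min + box,
      y_max = .data$y_min + box,
      confidence = .data$score
    ) %>%
    select(
      "observer_id", "patient_id", "slice_id",
      "x_min", "y_min", "x_max", "y_max", "confidence", "session"
    )

  reference <- tibble(
    slice_id = slice_id,
    patient_id = patient_id,
    label = ifelse(truth == 1L, "positive", "negative")
  )
  profiles <- obs %>%
    select(
      "observer_id", "years_experience", "cine_cases", "adhesion_cases",
      "clinical_threshold_pct", "is_consensus"
    )

  structure(
    list(
      annotations = ann,
      profiles = profiles,
      reference = reference,
      latent = latent,
      config = config
    ),
    class = "simulated_study"
  )
}

draw_truth <- function(config, counts, patient_id, n_slices) {
  if (is.null(config$n_positive_slices)) {
    return(rbinom(n_slices, 1L, config$slice_prevalence))
  }
  n_pos <- config$n_positive_slices
  if (n_pos < 1 || n_pos > n_slices) abort("n_positive_slices out of range")
  truth <- integer(n_slices)
  if (is.null(config$n_negative_patients)) {
    truth[sample.int(n_slices, n_pos)] <- 1L
    return(truth)
  }
  patients <- unique(patient_id)
  n_neg_pat <- config$n_negative_patients
  if (n_neg_pat >= length(patients)) abort("too many negative patients")
  neg_pat <- sample(patients, n_neg_pat)
  pos_pat <- setdiff(patients, neg_pat)
  if (n_pos < length(pos_pat)) {
    abort("n_positive_slices must cover every positive patient")
  }
  eligible <- which(patient_id %in% pos_pat)
  # one guaranteed positive slice per positive patient, remainder at random
  first <- vapply(
    pos_pat,
    function(p) {
      idx <- which(patient_id == p)
      idx[sample.int(length(idx), 1L)]
    },
    integer(1)
  )
  pool <- setdiff(eligible, first)
  rest <- pool[sample.int(length(pool), n_pos - length(first))]
  truth[c(first, rest)] <- 1L
  truth
}

#' Continuous-score AUC of the latent model
#'
#' Under the equal-variance binormal model with a shared case effect of
#' standard deviation `sigma_c`, the continuous latent signal of a reader
#' with discrimination `d` separates positive from negative slices with
#' AUC = Phi(d / sqrt(2 * (1 + sigma_c^2))).
#'
#' @param d Discrimination (standardized mean shift), >= 0.
#' @param sigma_c Case-effect standard deviation, >= 0.
#' @return AUC in \[0.5, 1\].
#' @export
theoretical_auc <- function(d, sigma_c = 0) {
  stopifnot(all(d >= 0), all(sigma_c >= 0))
  pnorm(d / sqrt(2 * (1 + sigma_c^2)))
}

#' Discrimination needed for a target continuous-score AUC
#'
#' Inverts [theoretical_auc()]: returns the d with
#' `theoretical_auc(d, sigma_c) == auc`.
#'
#' @param auc Target AUC in \[0.5, 1).
#' @param sigma_c Case-effect standard deviation.
#' @return The discrimination d.
#' @export
discrimination_for_auc <- function(auc, sigma_c = 0) {
  stopifnot(all(auc >= 0.5), all(auc < 1))
  qnorm(auc) * sqrt(2 * (1 + sigma_c^2))
}

#' The canonical observer panel of the motivating study design
#'
#' Fifteen readers with their years of general experience (including
#' residency), cine-MRI cases reviewed, adhesion cine-MRI cases reviewed and
#' clinical-significance thresholds; the first three formed the consensus
#' panel that set the reference standard.
#'
#' @return An observer-profile tibble (see [read_observers()]).
#' @export
benchmark_observers <- function() {
  tibble(
    observer_id = sprintf("obs%02d", 1:15),
    years_experience = c(4L, 30L, 0L, 6L, 15L, 5L, 7L, 6L, 17L, 2L, 2L, 2L,
                         3L, 3L, 4L),
    cine_cases = c(30L, 100L, 0L, 30L, 100L, 150L, 50L, 30L, 0L, 15L, 0L,
                   0L, 0L, 50L, 20L),
    adhesion_cases = c(30L, 100L, 0L, 30L, 0L, 0L, 50L, 30L, 0L, 15L, 0L,
                       0L, 0L, 0L, 20L),
    clinical_threshold_pct = c(40L, 80L, 60L, 40L, 20L, 40L, 80L, 40L, 0L,
                               40L, 0L, 60L, 60L, 40L, 60L),
    is_consensus = c(TRUE, TRUE, TRUE, rep(FALSE, 12))
  )
}

#' Simulate a study with the canonical design
#'
#' A synthetic stand-in for the motivating observer study's (non-public)
#' annotations: 10 patients, 61 sagittal slices (9 patients with 6 slices,
#' one with 7), exactly 19 positive slices spread over 7 positive patients (3
#' patients fully negative), and the 15-reader panel of
#' [benchmark_observers()]. Both reader discrimination and the loading on the
#' shared case effect increase with experience: `d = d_low` plus
#' `d_year_bonus` / `d_cine_bonus` for the high-year / high-cine groups
#' (default cutoffs), and `case_loading = loading_low` plus
#' `loading_year_bonus` / `loading_cine_bonus` likewise; consensus readers
#' get the maxima of both. Experienced readers thus both detect adhesions
#' better and share more perception with one another, which is what makes
#' their group agreement exceed the inexperienced groups'. Readers obs02,
#' obs03, obs04, obs07 and obs15 read twice.
#'
#' @param seed Integer seed.
#' @param d_low Baseline discrimination of inexperienced readers.
#' @param d_year_bonus,d_cine_bonus Additive discrimination for high-year /
#'   high-cine readers.
#' @param loading_low Baseline case-effect loading.
#' @param loading_year_bonus,loading_cine_bonus Additive loading for
#'   high-year / high-cine readers.
#' @param ... Further arguments passed to [sim_config()] (e.g.
#'   `case_effect_sd`, `intra_session_noise`).
#' @return A `simulated_study` object.
#' @export
simulate_benchmark_study <- function(seed = 1L, d_low = 0.85,
                                     d_year_bonus = 0.4,
                                     d_cine_bonus = 0.4,
                                     loading_low = 0.4,
                                     loading_year_bonus = 0.5,
                                     loading_cine_bonus = 0.5, ...) {
  panel <- benchmark_observers()
  cuts <- group_cutoffs()
  high_year <- panel$years_experience >= cuts$years_cutoff
  high_cine <- panel$cine_cases >= cuts$cine_cutoff
  d <- d_low + d_year_bonus * high_year + d_cine_bonus * high_cine
  d[panel$is_consensus] <- d_low + d_year_bonus + d_cine_bonus
  lam <- loading_low + loading_year_bonus * high_year +
    loading_cine_bonus * high_cine
  lam[panel$is_consensus] <- loading_low + loading_year_bonus +
    loading_cine_bonus
  panel$d <- d
  panel$case_loading <- lam
  panel$n_sessions <- ifelse(
    panel$observer_id %in% c("obs02", "obs03", "obs04", "obs07", "obs15"),
    2L, 1L
  )
  config <- sim_config(
    observers = panel,
    n_patients = 10L,
    slices_per_patient = c(rep(6L, 9), 7L),
    slice_prevalence = 19 / 61,
    n_positive_slices = 19L,
    n_negative_patients = 3L,
    seed = seed,
    ...
  )
  simulate_study(config)
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study: %d patients, %d slices (%d positive), %d observers, %d annotations>\n",
    length(unique(x$reference$patient_id)),
    nrow(x$reference),
    sum(x$reference$label == "positive"),
    nrow(x$profiles),
    nrow(x$annotations)
  ))
  invisible(x)
}
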