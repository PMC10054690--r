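#' Reduce box annotations to a slice-by-observer score table
#'
#' Every observer reviews every slice; a slice the observer did not annotate
#' scores 0, and a slice with one or more boxes scores the maximum confidence
#' over those boxes (the conventional reduction from free-response box marks
#' to a case-level rating). The result has one row per slice and one ordinal
#' score column per observer, values in 0..5.
#'
#' @param annotations A tibble of annotation records (see
#'   [read_annotations()]).
#' @param slices Character vector of all slice ids in the study, in the row
#'   order wanted.
#' @param observers Character vector of all observer ids, in the column order
#'   wanted.
#' @param session Reading session to extract (1 or 2).
#' @return A tibble with column `slice_id` followed by one integer column per
#'   observer.
#' @export
slice_scores <- function(annotations, slices, observers, session = 1L) {
  annotations <- validate_annotations(annotations)
  if (!all(annotations$slice_id %in% slices)) {
    abort("annotation refers to a slice_id not in `slices`")
  }
  if (!all(annotations$observer_id %in% observers)) {
    abort("annotation refers to an observer_id not in `observers`")
  }
  ses <- session
  cells <- annotations %>%
    filter(.data$session == ses) %>%
    group_by(.data$slice_id, .data$observer_id) %>%
    summarise(score = max(.data$confidence), .groups = "drop")
  grid <- tidyr::expand_grid(slice_id = slices, observer_id = observers)
  grid %>%
    left_join(cells, by = c("slice_id", "observer_id")) %>%
    mutate(score = as.integer(tidyr::replace_na(.data$score, 0L))) %>%
    tidyr::pivot_wider(names_from = "observer_id", values_from = "score") %>%
    as_tibble()
}

#' Binarize ordinal confidence scores at each reader's clinical threshold
#'
#' A score of c on the 5-point scale is read as 20c% certainty. A cell is
#' positive iff the slice was annotated at all (score > 0) and the certainty
#' reaches the reader's clinical-significance threshold (`score * 20 >=
#' clinical_threshold_pct`, "at least"). A 0% threshold therefore counts any
#' annotation as positive, while an unannotated slice is never positive.
#'
#' @param scores A slice-by-observer score table from [slice_scores()].
#' @param observers Observer profiles (see [read_observers()]); every score
#'   column must have a profile.
#' @return A tibble with column `slice_id` followed by one logical column per
#'   observer (`TRUE` = positive call).
#' @export
binarize_scores <- function(scores, observers) {
  observers <- validate_observers(observers)
  obs_cols <- setdiff(names(scores), "slice_id")
  missing <- setdiff(obs_cols, observers$observer_id)
  if (length(missing) > 0) {
    abort(paste0(
      "no profile for observer(s): ", paste(missing, collapse = ", ")
    ))
  }
  thr <- setNames(observers$clinical_threshold_pct, observers$observer_id)
  out <- scores
  for (ob in obs_cols) {
    s <- scores[[ob]]
    out[[ob]] <- s > 0L & s * 20L >= thr[[ob]]
  }
  out
}

#' Experience-group cutoffs
#'
#' Readers are split into low/high groups on three axes of experience. The
#' defaults place a reader in the high group at >= 5 years of general
#' experience (including residency), >= 30 cine-MRI cases reviewed of any
#' type, and >= 2 adhesion cine-MRI cases reviewed.
#'
#' @param years_cutoff,cine_cutoff,adhesion_cutoff Positive cutoffs; a reader
#'   at or above the cutoff is in the high group for that axis.
#' @return A named list of cutoffs.
#' @export
group_cutoffs <- function(years_cutoff = 5L, cine_cutoff = 30L,
                          adhesion_cutoff = 2L) {
  stopifnot(years_cutoff > 0, cine_cutoff > 0, adhesion_cutoff > 0)
  list(
    years_cutoff = years_cutoff,
    cine_cutoff = cine_cutoff,
    adhesion_cutoff = adhesion_cutoff
  )
}

#' Assign observers to experience groups
#'
#' Consensus-panel members belong to the consensus group only; their
#' experience-axis groups are `NA`. Every other reader is low or high on each
#' of the three axes, at the cutoffs in `cutoffs`.
#'
#' @param observers Observer profiles (see [read_observers()]).
#' @param cutoffs A list from [group_cutoffs()].
#' @return The profiles with added character columns `year_group`,
#'   `cine_group`, `adhesion_group` ("low"/"high", `NA` for consensus).
#' @export
assign_groups <- function(observers, cutoffs = group_cutoffs()) {
  observers <- validate_observers(observers)
  lowhigh <- function(x, cutoff) ifelse(x >= cutoff, "high", "low")
  observers %>%
    mutate(
      year_group = ifelse(
        .data$is_consensus, NA_character_,
        lowhigh(.data$years_experience, cutoffs$years_cutoff)
      ),
      cine_group = ifelse(
        .data$is_consensus, NA_character_,
        lowhigh(.data$cine_cases, cutoffs$cine_cutoff)
      ),
      adhesion_group = ifelse(
        .data$is_consensus, NA_character_,
        lowhigh(.data$adhesion_cases, cutoffs$adhesion_cutoff)
      )
    )
}

#' Enumerate group memberships in long form
#'
#' @inheritParams assign_groups
#' @return A tibble with columns `group` (one of `consensus`, `low-year`,
#'   `high-year`, `low-cine`, `high-cine`, `low-adhesion`, `high-adhesion`)
#'   and `observer_id`. Non-consensus readers appear in three groups;
#'   consensus readers only in `consensus`.
#' @export
group_members <- function(observers, cutoffs = group_cutoffs()) {
  assigned <- assign_groups(observers, cutoffs)
  long <- assigned %>%
    tidyr::pivot_longer(
      c("year_group", "cine_group", "adhesion_group"),
      names_to = "axis", values_to = "side"
    ) %>%
    filter(!is.na(.data$side)) %>%
    mutate(group = paste0(.data$side, "-", sub("_group$", "", .data$axis))) %>%
    select("group", "observer_id")
  consensus <- assigned %>%
    filter(.data$is_consensus) %>%
    mutate(group = "consensus") %>%
    select("group", "observer_id")
  groups <- c(
    "consensus", "low-year", "high-year", "low-cine", "high-cine",
    "low-adhesion", "high-adhesion"
  )
  bind_rows(consensus, long) %>%
    mutate(group = factor(.data$group, levels = groups)) %>%
    arrange(.data$group, .data$observer_id) %>%
    mutate(group = as.character(.data$group))
}

#' Summarise a patient cohort's label composition
#'
#' @param patients A tibble with columns `patient_id` and `label`
#'   ("positive"/"negative"), e.g. from [patient_labels()].
#' @return A one-row tibble with `n_patients`, `n_negative` and
#'   `pct_negative`, the negative share as an integer percent (half-up
#'   rounding, so the positive and negative percentages may sum to 101 or 99
#'   after rounding).
#' @export
cohort_summary <- function(patients) {
  stopifnot(all(c("patient_id", "label") %in% names(patients)))
  if (nrow(patients) == 0) abort("empty cohort")
  if (!all(patients$label %in% c("positive", "negative"))) {
    abort("labels must be 'positive' or 'negative'")
  }
  n <- nrow(patients)
  n_neg <- sum(patients$label == "negative")
  tibble(
    n_patients = n,
    n_negative = n_neg,
    pct_negative = as.integer(floor(100 * n_neg / n + 0.5))
  )
}

#' Stratified random sample of patients, preserving prevalence
#'
#' Samples the same fraction from the positive and negative patient strata
#' without replacement, so the relative prevalence of the cohort is carried
#' into the subset.
#'
#' @inheritParams cohort_summary
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed; the same seed always yields the same subset.
#' @param rounding How to round the per-stratum count `fraction * n`:
#'   `"ceiling"` (default), `"floor"` or `"round"`.
#' @return The sampled rows of `patients`, ordered as in the input.
#' @export
stratified_sample <- function(patients, fraction, seed,
                              rounding = c("ceiling", "floor", "round")) {
  if (!(fraction > 0 && fraction <= 1)) {
    abort("fraction must be in (0, 1]")
  }
  rounding <- arg_match(rounding)
  rounder <- switch(rounding, ceiling = ceiling, floor = floor, round = round)
  stopifnot(all(c("patient_id", "label") %in% names(patients)))
  withr::local_seed(seed)
  keep <- patients %>%
    group_by(.data$label) %>%
    slice_sample(prop = 1) %>% # shuffle within stratum
    filter(row_number() <= rounder(fraction * n())) %>%
    ungroup() %>%
    pull(.data$patient_id)
  filter(patients, .data$patient_id %in% keep)
}
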