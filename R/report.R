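#' Run the full observer-variability and diagnostic-accuracy analysis
#'
#' End-to-end pipeline: slice-level scoring of the annotations, binarization
#' at each reader's clinical threshold, experience grouping, per-group
#' agreement statistics (Fleiss' kappa and unanimity percentage agreement
#' with case-bootstrap confidence intervals), per-group diagonally averaged
#' AUC with a two-way bootstrap interval, intra-observer statistics for
#' readers with a second session (Cohen's kappa, pairwise percentage
#' agreement), pairwise group comparisons (observer-permutation tests for the
#' agreement metrics, bootstrap z-tests for AUC), and per-observer ROC
#' curves. Consensus readers are excluded from all ROC computations, since
#' they define the reference standard; groups with fewer than two members are
#' reported as absent rather than erroring.
#'
#' The result is a pure function of `(annotations, observers, reference,
#' cutoffs, n_boot, n_perm, ci_level, seed)`: rerunning with the same seed
#' reproduces every number and output file bit for bit.
#'
#' @param annotations Annotation records (see [read_annotations()]).
#' @param observers Observer profiles (see [read_observers()]).
#' @param reference Slice-level reference standard (see [read_reference()]).
#' @param cutoffs Experience-group cutoffs from [group_cutoffs()].
#' @param n_boot Bootstrap resamples for confidence intervals (default 2000).
#' @param n_perm Permutations for group-difference tests (default 10000).
#' @param ci_level Confidence level (default 0.95).
#' @param seed Integer seed (mandatory: every resampling stage derives its
#'   own stream from it).
#' @param out_dir Optional directory; when given, the tables are written as
#'   CSV files plus a JSON run manifest (see [write_report()]).
#' @return A `reader_study_report` object: a list of tibbles
#'   `inter_observer`, `intra_observer`, `comparisons`, `roc_points`,
#'   `group_roc_points`, `cohort`, plus `roc_curves` (named list of
#'   `roc_curve` objects) and `manifest`.
#' @export
run_analysis <- function(annotations, observers, reference,
                         cutoffs = group_cutoffs(),
                         n_boot = 2000L, n_perm = 10000L, ci_level = 0.95,
                         seed, out_dir = NULL) {
  stage <- "validate inputs"
  report <- tryCatch(
    {
      annotations <- validate_annotations(annotations)
      observers <- validate_observers(observers)
      reference <- validate_reference(reference)
      if (sum(!observers$is_consensus) < 2) {
        abort("need at least 2 non-consensus observers")
      }

      stage <- "slice scoring"
      scores <- slice_scores(
        annotations, reference$slice_id, observers$observer_id, session = 1L
      )
      labels <- binarize_scores(scores, observers)
      truth <- reference$label == "positive"
      members <- group_members(observers, cutoffs)
      groups <- split(members$observer_id, members$group)
      groups <- groups[vapply(groups, length, integer(1)) >= 2]

      stage <- "inter-observer agreement"
      seeds <- seed_stream(seed)
      inter <- purrr::imap(groups, function(ids, g) {
        lab <- labels[ids]
        fk <- bootstrap_ci(lab, "fleiss_kappa", n_boot, ci_level,
                           seed = seeds("fleiss", g))
        pa <- bootstrap_ci(lab, "pct_agreement", n_boot, ci_level,
                           seed = seeds("pct", g))
        tibble(
          group = g, n_observers = length(ids),
          fleiss_kappa = fk$value, fleiss_ci_low = fk$ci_low,
          fleiss_ci_high = fk$ci_high,
          fleiss_band = kappa_interpretation(min(1, max(-1, fk$value))),
          pct_agreement = pa$value, pct_ci_low = pa$ci_low,
          pct_ci_high = pa$ci_high
        )
      }) %>% bind_rows()

      stage <- "group AUC"
      roc_groups <- groups[names(groups) != "consensus"]
      auc_tbl <- purrr::imap(roc_groups, function(ids, g) {
        group_auc_summary(scores[c("slice_id", ids)], reference,
                          n_boot = n_boot, ci_level = ci_level,
                          seed = seeds("auc", g), group = g)
      }) %>% bind_rows()
      inter <- left_join(
        inter,
        select(auc_tbl, "group", "mean_auc",
               auc_ci_low = "ci_low", auc_ci_high = "ci_high"),
        by = "group"
      )

      stage <- "intra-observer agreement"
      second <- sort(unique(
        annotations$observer_id[annotations$session == 2L]
      ))
      intra <- purrr::map(second, function(ob) {
        ob_ann <- filter(annotations, .data$observer_id == ob)
        s2 <- slice_scores(ob_ann, reference$slice_id, ob, session = 2L)
        lab2 <- binarize_scores(s2, observers)
        pair <- tibble(s1 = labels[[ob]], s2 = lab2[[ob]])
        ck <- bootstrap_ci(pair, "cohen_kappa", n_boot, ci_level,
                           seed = seeds("cohen", ob))
        pa <- bootstrap_ci(pair, "pct_agreement", n_boot, ci_level,
                           seed = seeds("cohen_pct", ob))
        tibble(
          observer_id = ob,
          is_consensus = observers$is_consensus[
            observers$observer_id == ob
          ],
          cohen_kappa = ck$value, cohen_ci_low = ck$ci_low,
          cohen_ci_high = ck$ci_high,
          cohen_band = kappa_interpretation(min(1, max(-1, ck$value))),
          pct_agreement = pa$value, pct_ci_low = pa$ci_low,
          pct_ci_high = pa$ci_high
        )
      }) %>% bind_rows()

      stage <- "group comparisons"
      comparisons <- compare_groups(
        labels, scores, reference, groups, n_boot, n_perm, seeds
      )

      stage <- "ROC curves"
      readers <- observers$observer_id[!observers$is_consensus]
      roc_curves <- setNames(
        lapply(readers, function(ob) {
          roc_curve(scores[[ob]], truth, observer_id = ob)
        }),
        readers
      )
      roc_points <- bind_rows(lapply(roc_curves, tidy))
      group_curves <- purrr::imap(roc_groups, function(ids, g) {
        avg <- diagonal_average(unname(roc_curves[ids]))
        mutate(tidy(avg), group = g, .before = 1)
      }) %>% bind_rows()

      stage <- "manifest"
      manifest <- list(
        package = "readervar",
        version = as.character(utils::packageVersion("readervar")),
        seed = as.integer(seed),
        n_boot = as.integer(n_boot),
        n_perm = as.integer(n_perm),
        ci_level = ci_level,
        cutoffs = cutoffs,
        n_slices = nrow(reference),
        n_observers = nrow(observers),
        n_annotations = nrow(annotations),
        groups = lapply(groups, as.character),
        input_hash = rlang::hash(list(annotations, observers, reference)),
        config_hash = rlang::hash(list(cutoffs, n_boot, n_perm, ci_level,
                                       seed))
      )

      structure(
        list(
          inter_observer = inter,
          intra_observer = intra,
          comparisons = comparisons,
          roc_curves = roc_curves,
          roc_points = roc_points,
          group_roc_points = group_curves,
          cohort = cohort_summary(patient_labels(reference)),
          manifest = manifest
        ),
        class = "reader_study_report"
      )
    },
    error = function(e) {
      abort(paste0("analysis failed at stage '", stage, "': ",
                   conditionMessage(e)), parent = e)
    }
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

compare_groups <- function(labels, scores, reference, groups,
                           n_boot, n_perm, seeds) {
  axes <- c("year", "cine", "adhesion")
  out <- list()
  for (ax in axes) {
    hi <- paste0("high-", ax)
    lo <- paste0("low-", ax)
    if (!all(c(hi, lo) %in% names(groups))) next
    for (metric in c("fleiss_kappa", "pct_agreement")) {
      out[[length(out) + 1]] <- permutation_test(
        labels[groups[[hi]]], labels[groups[[lo]]],
        metric = metric, n_perm = n_perm,
        seed = seeds("perm", paste(metric, ax)),
        group_a = hi, group_b = lo
      )
    }
    aucd <- compare_group_auc(
      scores[c("slice_id", groups[[hi]])],
      scores[c("slice_id", groups[[lo]])],
      reference, n_boot = n_boot,
      seed = seeds("auccmp", ax), group_a = hi, group_b = lo
    )
    out[[length(out) + 1]] <- tibble(
      metric = "mean_auc", group_a = hi, group_b = lo,
      delta = aucd$delta, p_value = aucd$p_value,
      z = aucd$z
    )
  }
  if ("consensus" %in% names(groups)) {
    others <- setdiff(names(groups), "consensus")
    for (g in others) {
      for (metric in c("fleiss_kappa", "pct_agreement")) {
        out[[length(out) + 1]] <- permutation_test(
          labels[groups[["consensus"]]], labels[groups[[g]]],
          metric = metric, n_perm = n_perm,
          seed = seeds("perm-consensus", paste(metric, g)),
          group_a = "consensus", group_b = g
        )
      }
    }
  }
  bind_rows(out) %>%
    mutate(significant = .data$p_value < 0.05) %>%
    select("metric", "group_a", "group_b", "delta", dplyr::any_of("z"),
           "p_value", "significant", dplyr::everything())
}

# Deterministic per-stage seed stream: independent small-integer seeds keyed
# by (stage, label), derived from the master seed.
seed_stream <- function(seed) {
  function(stage, label) {
    key <- rlang::hash(list(as.integer(seed), stage, label))
    # fold the first 7 hex digits into a positive 32-bit integer
    as.integer(strtoi(substr(key, 1, 7), base = 16L))
  }
}

#' Write a report bundle to disk
#'
#' Emits `inter_observer.csv`, `intra_observer.csv`, `comparisons.csv`,
#' `roc_curves.csv` (per-observer points), `group_roc_curves.csv`
#' (diagonally averaged group curves), `cohort.csv` and `manifest.json`.
#'
#' @param report A `reader_study_report` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "reader_study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$inter_observer, file.path(dir, "inter_observer.csv"),
                   eol = "\n")
  readr::write_csv(report$intra_observer, file.path(dir, "intra_observer.csv"),
                   eol = "\n")
  readr::write_csv(report$comparisons, file.path(dir, "comparisons.csv"),
                   eol = "\n")
  readr::write_csv(report$roc_points, file.path(dir, "roc_curves.csv"),
                   eol = "\n")
  readr::write_csv(report$group_roc_points,
                   file.path(dir, "group_roc_curves.csv"), eol = "\n")
  readr::write_csv(report$cohort, file.path(dir, "cohort.csv"), eol = "\n")
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Run the analysis on a study directory
#'
#' Reads `annotations.csv`, `observers.csv` and `reference.csv` from `dir`
#' (the dialect written by [write_study()]) and calls [run_analysis()].
#'
#' @param dir Directory containing the three CSV files.
#' @inheritParams run_analysis
#' @inheritDotParams run_analysis -annotations -observers -reference
#' @return A `reader_study_report`.
#' @export
analyze_study_dir <- function(dir, ...) {
  run_analysis(
    annotations = read_annotations(file.path(dir, "annotations.csv")),
    observers = read_observers(file.path(dir, "observers.csv")),
    reference = read_reference(file.path(dir, "reference.csv")),
    ...
  )
}

#' @export
print.reader_study_report <- function(x, ...) {
  cat("<reader_study_report>\n")
  cat(sprintf("  %d slices, %d observers, seed %d\n",
              x$manifest$n_slices, x$manifest$n_observers, x$manifest$seed))
  cat("  inter-observer agreement:\n")
  print(select(x$inter_observer, "group", "fleiss_kappa", "pct_agreement",
               "mean_auc"), n = Inf)
  invisible(x)
}

#' @export
tidy.reader_study_report <- function(x, ...) {
  x$inter_observer
}

#' @export
glance.reader_study_report <- function(x, ...) {
  tibble(
    n_slices = x$manifest$n_slices,
    n_observers = x$manifest$n_observers,
    n_groups = nrow(x$inter_observer),
    n_repeat_readers = nrow(x$intra_observer),
    seed = x$manifest$seed
  )
}

#' Plot the per-observer and group-average ROC curves of a report
#'
#' @param object A `reader_study_report`.
#' @param ... Unused.
#' @return A ggplot object: one panel per experience grouping, individual
#'   reader curves in grey and the diagonally averaged group curves in
#'   colour.
#' @export
autoplot.reader_study_report <- function(object, ...) {
  grp <- object$group_roc_points %>%
    tidyr::separate_wider_delim("group", "-", names = c("side", "axis"))
  ind <- object$roc_points
  ggplot2::ggplot() +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey70") +
    ggplot2::geom_path(
      data = ind,
      ggplot2::aes(x = .data$fpr, y = .data$tpr, group = .data$observer_id),
      colour = "grey60", linewidth = 0.3
    ) +
    ggplot2::geom_path(
      data = grp,
      ggplot2::aes(x = .data$fpr, y = .data$tpr, colour = .data$side),
      linewidth = 0.9
    ) +
    ggplot2::facet_wrap(~axis) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "experience") +
    ggplot2::theme_minimal()
}
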