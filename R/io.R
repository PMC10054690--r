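#' Read and write annotation tables
#'
#' An annotation table records one bounding box per row: the observer who
#' placed it, the patient and slice it belongs to, the box corners in pixel
#' coordinates (origin top-left, 0-based, maximum-exclusive) and the ordinal
#' confidence on the 5-point scale, together with the reading-session index
#' (1 for the first read, 2 for a repeat read).
#'
#' Files are comma-separated UTF-8 text with a header and LF line endings;
#' `write_annotations()` followed by `read_annotations()` round-trips both the
#' records and the bytes of the file.
#'
#' @param path Path to a CSV file with columns `observer_id`, `patient_id`,
#'   `slice_id`, `x_min`, `y_min`, `x_max`, `y_max`, `confidence`, `session`.
#' @return A tibble of validated annotation records.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' ann <- tibble::tibble(
#'   observer_id = "obs01", patient_id = "pat01", slice_id = "sl001",
#'   x_min = 10L, y_min = 20L, x_max = 40L, y_max = 60L,
#'   confidence = 4L, session = 1L
#' )
#' write_annotations(ann, path)
#' read_annotations(path)
read_annotations <- function(path) {
  df <- read_checked(
    path,
    readr::cols(
      observer_id = readr::col_character(),
      patient_id = readr::col_character(),
      slice_id = readr::col_character(),
      x_min = readr::col_integer(),
      y_min = readr::col_integer(),
      x_max = readr::col_integer(),
      y_max = readr::col_integer(),
      confidence = readr::col_integer(),
      session = readr::col_integer()
    )
  )
  validate_annotations(df)
}

#' @rdname read_annotations
#' @param annotations A tibble of annotation records, as returned by
#'   [read_annotations()] or [simulate_study()].
#' @export
write_annotations <- function(annotations, path) {
  annotations <- validate_annotations(annotations)
  readr::write_csv(annotations, path, eol = "\n")
  invisible(path)
}

#' Read and write observer profile tables
#'
#' Observer profiles carry the experience fields used for grouping readers
#' (years of general radiological experience including residency, number of
#' cine-MRI cases reviewed, number of adhesion cine-MRI cases reviewed), the
#' per-reader clinical-significance threshold (the minimum confidence,
#' expressed in percent, at which the reader would call a finding positive in
#' practice; a multiple of 20 on the 5-point scale) and a flag marking the
#' readers who formed the consensus panel that set the reference standard.
#'
#' @param path Path to a CSV file with columns `observer_id`,
#'   `years_experience`, `cine_cases`, `adhesion_cases`,
#'   `clinical_threshold_pct`, `is_consensus`.
#' @return A tibble of validated observer profiles.
#' @export
read_observers <- function(path) {
  df <- read_checked(
    path,
    readr::cols(
      observer_id = readr::col_character(),
      years_experience = readr::col_integer(),
      cine_cases = readr::col_integer(),
      adhesion_cases = readr::col_integer(),
      clinical_threshold_pct = readr::col_integer(),
      is_consensus = readr::col_logical()
    )
  )
  validate_observers(df)
}

#' @rdname read_observers
#' @param observers A tibble of observer profiles.
#' @export
write_observers <- function(observers, path) {
  observers <- validate_observers(observers)
  readr::write_csv(observers, path, eol = "\n")
  invisible(path)
}

#' Read and write the slice-level reference standard
#'
#' The reference standard labels every slice `"positive"` or `"negative"`.
#' Patient-level labels are derived, not stored: a patient is positive if and
#' only if at least one of its slices is positive (see [patient_labels()]).
#'
#' @param path Path to a CSV file with columns `slice_id`, `patient_id`,
#'   `label`.
#' @return A tibble with one row per slice.
#' @export
read_reference <- function(path) {
  df <- read_checked(
    path,
    readr::cols(
      slice_id = readr::col_character(),
      patient_id = readr::col_character(),
      label = readr::col_character()
    )
  )
  validate_reference(df)
}

#' @rdname read_reference
#' @param reference A tibble with columns `slice_id`, `patient_id`, `label`.
#' @export
write_reference <- function(reference, path) {
  reference <- validate_reference(reference)
  readr::write_csv(reference, path, eol = "\n")
  invisible(path)
}

#' Derive patient-level labels from the slice-level reference standard
#'
#' @param reference A reference-standard tibble (see [read_reference()]).
#' @return A tibble with columns `patient_id` and `label`; a patient is
#'   `"positive"` iff any of its slices is positive.
#' @export
patient_labels <- function(reference) {
  reference <- validate_reference(reference)
  reference %>%
    group_by(.data$patient_id) %>%
    summarise(
      label = if (any(.data$label == "positive")) "positive" else "negative",
      .groups = "drop"
    )
}

#' Write a simulated study to a directory in the package's CSV dialect
#'
#' Produces `annotations.csv`, `observers.csv` and `reference.csv`, the same
#' files [read_annotations()], [read_observers()] and [read_reference()]
#' consume, so a simulated study can stand in for a real annotation export.
#'
#' @param study A `simulated_study` object from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_annotations(study$annotations, file.path(dir, "annotations.csv"))
  write_observers(study$profiles, file.path(dir, "observers.csv"))
  write_reference(study$reference, file.path(dir, "reference.csv"))
  invisible(dir)
}

# readr-based reader that converts parse problems into hard errors naming the
# offending file line (readr's problem rows already count the header line).
read_checked <- function(path, col_types) {
  if (!file.exists(path)) {
    abort(paste0("file does not exist: ", path))
  }
  df <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, progress = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(paste0(
      "malformed row in ", basename(path), " at line ", probs$row[1],
      ": expected ", probs$expected[1], ", got ", probs$actual[1]
    ))
  }
  missing <- setdiff(names(col_types$cols), names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "missing column(s) in ", basename(path), ": ",
      paste(missing, collapse = ", ")
    ))
  }
  as_tibble(df)
}

validate_annotations <- function(df) {
  required <- c(
    "observer_id", "patient_id", "slice_id",
    "x_min", "y_min", "x_max", "y_max", "confidence", "session"
  )
  check_columns(df, required, "annotations")
  df <- as_tibble(df)[required]
  bad_conf <- which(!(df$confidence %in% 1:5))
  if (length(bad_conf) > 0) {
    abort(paste0(
      "confidence must be in 1..5; violated at record ", bad_conf[1],
      " (value ", df$confidence[bad_conf[1]], ")"
    ))
  }
  bad_box <- which(!(df$x_min < df$x_max & df$y_min < df$y_max))
  if (length(bad_box) > 0) {
    abort(paste0("degenerate bounding box at record ", bad_box[1]))
  }
  if (!all(df$session %in% 1:2)) {
    abort("session must be 1 or 2")
  }
  slice_map <- distinct(df, .data$slice_id, .data$patient_id)
  if (anyDuplicated(slice_map$slice_id) > 0) {
    abort("a slice_id maps to more than one patient_id")
  }
  df
}

validate_observers <- function(df) {
  required <- c(
    "observer_id", "years_experience", "cine_cases", "adhesion_cases",
    "clinical_threshold_pct", "is_consensus"
  )
  check_columns(df, required, "observers")
  df <- as_tibble(df)[required]
  if (anyDuplicated(df$observer_id) > 0) abort("duplicate observer_id")
  counts <- c(df$years_experience, df$cine_cases, df$adhesion_cases)
  if (any(counts < 0)) abort("experience fields must be non-negative")
  if (!all(df$clinical_threshold_pct %in% seq(0L, 100L, by = 20L))) {
    abort("clinical_threshold_pct must be a multiple of 20 in 0..100")
  }
  if (!is.logical(df$is_consensus) || anyNA(df$is_consensus)) {
    abort("is_consensus must be TRUE/FALSE")
  }
  df
}

validate_reference <- function(df) {
  required <- c("slice_id", "patient_id", "label")
  check_columns(df, required, "reference")
  df <- as_tibble(df)[required]
  if (anyDuplicated(df$slice_id) > 0) abort("duplicate slice_id in reference")
  if (!all(df$label %in% c("positive", "negative"))) {
    abort("reference labels must be 'positive' or 'negative'")
  }
  df
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "missing column(s) in ", what, ": ", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
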