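#' Read a wide-format Kano survey CSV
#'
#' The canonical input: a UTF-8, comma-separated file with a
#' `respondent_id` column followed, per attribute `X`, by columns `X_func`
#' and `X_dysf`. Cells may hold integer codes 1-5, the English option
#' labels, or be empty (missing). Column order is free. Validation errors
#' name the offending column and value; per-column missingness is reported
#' as a message.
#'
#' @param path CSV file path.
#' @param manifest Optional attribute manifest (data frame or path to a
#'   manifest CSV with columns `attribute`, `dimension`, and optionally
#'   `wording`, `dimension_name`); columns not covered by the manifest are
#'   an error.
#' @return A [kano_survey()] object.
#' @export
read_survey_csv <- function(path, manifest = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (is.character(manifest) && length(manifest) == 1) {
    manifest <- readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
  }
  svy <- kano_survey(raw, manifest = manifest)
  miss <- vapply(svy$data[setdiff(names(svy$data), "respondent_id")],
                 function(col) sum(is.na(col)), integer(1))
  if (any(miss > 0)) {
    top <- miss[miss > 0]
    message("missing answers in ", sum(top), " cell(s): ",
            paste(names(top), top, sep = "=", collapse = ", "))
  }
  svy
}

#' Read a survey from long format
#'
#' Convenience reader for data laid out as one row per (respondent,
#' attribute, polarity) triple.
#'
#' @param x Data frame or CSV path with columns `respondent_id`,
#'   `attribute`, `polarity` (`"functional"`/`"dysfunctional"` or
#'   `"func"`/`"dysf"`) and `answer`.
#' @inheritParams read_survey_csv
#' @return A [kano_survey()] object.
#' @export
read_survey_long <- function(x, manifest = NULL) {
  if (is.character(x) && length(x) == 1) {
    x <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  }
  x <- tibble::as_tibble(x)
  stopifnot(all(c("respondent_id", "attribute", "polarity", "answer") %in% names(x)))
  pol <- c(functional = "func", dysfunctional = "dysf",
           func = "func", dysf = "dysf")[tolower(x$polarity)]
  if (anyNA(pol)) stop("unknown polarity value(s)", call. = FALSE)
  x$column <- paste0(x$attribute, "_", pol)
  wide <- tidyr::pivot_wider(x[c("respondent_id", "column", "answer")],
                             names_from = "column", values_from = "answer")
  kano_survey(wide, manifest = manifest)
}

#' Write a survey to the canonical wide CSV
#'
#' @param survey A [kano_survey()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(survey, path) {
  stopifnot(inherits(survey, "kano_survey"))
  readr::write_csv(survey$data, path, progress = FALSE)
  invisible(path)
}

.fmt_pct <- function(x) sprintf("%.2f%%", round_half_up(100 * x, 2))

#' Write the analysis results to a directory
#'
#' Writes the human-readable and machine-readable outputs of a survey run:
#'
#' * `indices.csv` — one row per attribute with Better and Worse as signed
#'   two-decimal percentages and the total satisfaction index, category
#'   strength and importance degree as two-decimal values, plus the
#'   assigned category;
#' * `summary.json` — category census, mean importance degree, the
#'   above-average attribute list, full-precision indices (fractions, not
#'   percent), and — when `reference` is supplied — the cell-by-cell
#'   discrepancy report from [compare_reference()];
#' * `quadrants.csv` — quadrant assignments, when supplied;
#' * `manifest.json` — echo of the run configuration for reproducibility.
#'
#' @param summary A [summarize_survey()] result.
#' @param out_dir Output directory (created if absent).
#' @param assignments Optional [quadrant_assign()] result.
#' @param reference Optional published reference table for auditing (see
#'   [compare_reference()]).
#' @param config Named list echoed into `manifest.json` (e.g. input paths,
#'   seed, thresholds).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(summary, out_dir, assignments = NULL,
                          reference = NULL, config = list()) {
  stopifnot(inherits(summary, "kano_summary"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()

  idx <- summary$indices
  report <- tibble::tibble(
    attribute = idx$attribute,
    better = .fmt_pct(idx$better),
    worse = .fmt_pct(idx$worse),
    total_satisfaction_index = sprintf("%.2f", round_half_up(idx$total_satisfaction, 2)),
    category_strength = sprintf("%.2f", round_half_up(idx$category_strength, 2)),
    importance_degree = sprintf("%.2f", round_half_up(idx$importance_degree, 2)),
    category = idx$category
  )
  f <- file.path(out_dir, "indices.csv")
  readr::write_csv(report, f, progress = FALSE)
  written <- c(written, f)

  summary_json <- list(
    n_attributes = nrow(idx),
    category_census = as.list(summary$category_census),
    mean_importance_degree = summary$mean_importance,
    above_average_ids = summary$above_average_ids,
    worse_mode = summary$worse_mode,
    tie_break = summary$tie_break,
    indices = idx
  )
  if (!is.null(reference)) {
    audit <- compare_reference(idx, reference)
    summary_json$reference_discrepancies <- audit[!audit$match, ]
  }
  f <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_json, f, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  written <- c(written, f)

  if (!is.null(assignments)) {
    f <- file.path(out_dir, "quadrants.csv")
    readr::write_csv(tibble::as_tibble(assignments), f, progress = FALSE)
    written <- c(written, f)
  }

  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    c(list(package = "kanodemand",
           version = as.character(utils::packageVersion("kanodemand"))),
      config),
    f, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  written <- c(written, f)
  invisible(written)
}
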