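#' Tabulate Kano category frequencies for one attribute
#'
#' Classifies each (functional, dysfunctional) answer pair with the
#' evaluation table and counts the six categories. Pairs with a missing
#' answer on either side are excluded before counting, so the six
#' frequencies sum to the number of complete pairs.
#'
#' @inheritParams classify_response
#' @return Named integer vector `c(f_M, f_O, f_A, f_I, f_R, f_Q)`.
#' @examples
#' tabulate_pairs(c(1, 2, 3), c(5, 5, 3))
#' @export
tabulate_pairs <- function(functional, dysfunctional,
                           table = kano_evaluation_table()) {
  cats <- classify_response(functional, dysfunctional, table = table)
  cats <- cats[!is.na(cats)]
  if (!length(cats)) stop("no classifiable responses", call. = FALSE)
  counts <- table(factor(cats, levels = kano_categories()))
  stats::setNames(as.integer(counts), paste0("f_", kano_categories()))
}

#' Tabulate category frequencies for every attribute of a survey
#'
#' @param survey A [kano_survey()] object.
#' @inheritParams classify_response
#' @return A tibble with one row per attribute: `attribute`, `f_M`, `f_O`,
#'   `f_A`, `f_I`, `f_R`, `f_Q` and `n_classifiable` (= f_M+f_O+f_A+f_I).
#' @examples
#' counts <- sports_demand_counts()
#' svy <- generate_from_counts(counts, seed = 1)
#' kano_tabulate(svy)
#' @export
kano_tabulate <- function(survey, table = kano_evaluation_table()) {
  stopifnot(inherits(survey, "kano_survey"))
  attrs <- survey_attributes(survey)
  rows <- lapply(attrs, function(a) {
    counts <- tryCatch(
      tabulate_pairs(survey$data[[paste0(a, "_func")]],
                     survey$data[[paste0(a, "_dysf")]],
                     table = table),
      error = function(e) {
        stop("attribute ", a, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    tibble::as_tibble_row(c(list(attribute = a), as.list(counts)))
  })
  out <- dplyr::bind_rows(rows)
  out$n_classifiable <- out$f_M + out$f_O + out$f_A + out$f_I
  out
}

.check_counts <- function(f_M, f_O, f_A, f_I) {
  if (any(c(f_M, f_O, f_A, f_I) < 0)) {
    stop("category counts must be non-negative", call. = FALSE)
  }
  n <- f_M + f_O + f_A + f_I
  if (any(n < 1)) {
    stop("no classifiable responses (f_M + f_O + f_A + f_I must be >= 1)",
         call. = FALSE)
  }
  n
}

#' Better coefficient (satisfaction index)
#'
#' The share of respondents for whom the attribute creates satisfaction:
#' (f_A + f_O) / (f_M + f_O + f_A + f_I). Reverse and questionable
#' responses are excluded from the denominator. Returned at full precision
#' as a fraction in \[0, 1\]; the reporting layer rounds and formats.
#'
#' @param f_M,f_O,f_A,f_I Per-attribute category frequencies (vectorised).
#' @return Numeric vector of fractions.
#' @examples
#' better_index(153, 114, 74, 95) # 188/436
#' @export
better_index <- function(f_M, f_O, f_A, f_I) {
  n <- .check_counts(f_M, f_O, f_A, f_I)
  (f_A + f_O) / n
}

#' Worse coefficient (dissatisfaction index)
#'
#' The (negative) share of respondents dissatisfied if the attribute is
#' absent. Two conventions are provided:
#'
#' * `"berger"` (default): -(f_O + f_M) / (f_M + f_O + f_A + f_I), the
#'   standard satisfaction/dissatisfaction coefficient;
#' * `"attractive_must"`: -(f_A + f_M) / (f_M + f_O + f_A + f_I), a variant
#'   that replaces the one-dimensional count with the attractive count,
#'   retained for fidelity to sources that typeset the formula that way.
#'
#' The bundled case-study reference values are consistent with `"berger"`
#' (see [compare_reference()]).
#'
#' @inheritParams better_index
#' @param mode `"berger"` or `"attractive_must"`.
#' @return Numeric vector of fractions in \[-1, 0\].
#' @examples
#' worse_index(118, 152, 71, 95) # -270/436
#' @export
worse_index <- function(f_M, f_O, f_A, f_I,
                        mode = c("berger", "attractive_must")) {
  mode <- match.arg(mode)
  n <- .check_counts(f_M, f_O, f_A, f_I)
  num <- if (mode == "berger") f_O + f_M else f_A + f_M
  -num / n
}

#' Importance degree
#'
#' Frequency-weighted importance score with weights 5 (must-be), 3
#' (one-dimensional), 1 (attractive) and 0 (indifferent):
#' (5 f_M + 3 f_O + 1 f_A) / (f_M + f_O + f_A + f_I). Ranges from 0
#' (all indifferent) to 5 (all must-be) and is used to rank attributes.
#'
#' @inheritParams better_index
#' @return Numeric vector in \[0, 5\].
#' @examples
#' importance_degree(179, 161, 61, 35) # 1439/436
#' @export
importance_degree <- function(f_M, f_O, f_A, f_I) {
  n <- .check_counts(f_M, f_O, f_A, f_I)
  (5 * f_M + 3 * f_O + 1 * f_A) / n
}

#' Total satisfaction index
#'
#' The share of classifiable respondents placing the attribute in one of the
#' three quality categories must-be, one-dimensional or attractive:
#' (f_M + f_O + f_A) / (f_M + f_O + f_A + f_I). Also called the total
#' category strength.
#'
#' @inheritParams better_index
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' total_satisfaction(166, 159, 78, 33) # 403/436
#' @export
total_satisfaction <- function(f_M, f_O, f_A, f_I) {
  n <- .check_counts(f_M, f_O, f_A, f_I)
  (f_M + f_O + f_A) / n
}

#' Category strength
#'
#' Decisiveness of the modal classification among the three quality
#' categories: (largest - second largest of f_M, f_O, f_A) divided by the
#' classifiable total. Zero when the top two quality categories tie.
#'
#' @inheritParams better_index
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' category_strength(95, 83, 154, 104) # (154 - 95)/436
#' @export
category_strength <- function(f_M, f_O, f_A, f_I) {
  n <- .check_counts(f_M, f_O, f_A, f_I)
  m <- cbind(f_M, f_O, f_A)
  top2 <- t(apply(m, 1, function(x) sort(x, decreasing = TRUE)[1:2]))
  unname((top2[, 1] - top2[, 2]) / n)
}

#' Modal Kano category of an attribute
#'
#' Assigns the category with the largest frequency among must-be,
#' one-dimensional, attractive and indifferent. Ties are resolved by a
#' configurable preference ordering, by default M > O > A > I (the most
#' conservative quality first).
#'
#' @inheritParams better_index
#' @param tie_break Character vector: a permutation of `c("M","O","A","I")`
#'   giving the preference order used on ties.
#' @return Character vector of category labels.
#' @examples
#' classify_attribute(105, 87, 134, 110) # "A"
#' classify_attribute(10, 10, 0, 0)      # tie -> "M" under the default order
#' @export
classify_attribute <- function(f_M, f_O, f_A, f_I,
                               tie_break = c("M", "O", "A", "I")) {
  if (!setequal(tie_break, c("M", "O", "A", "I")) || length(tie_break) != 4) {
    stop("`tie_break` must be a permutation of M, O, A, I", call. = FALSE)
  }
  .check_counts(f_M, f_O, f_A, f_I)
  counts <- cbind(M = f_M, O = f_O, A = f_A, I = f_I)[, tie_break, drop = FALSE]
  tie_break[apply(counts, 1, which.max)]
}

.as_counts_df <- function(counts) {
  counts <- tibble::as_tibble(counts)
  needed <- c("attribute", "f_M", "f_O", "f_A", "f_I")
  if (!all(needed %in% names(counts))) {
    stop("`counts` must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!"f_R" %in% names(counts)) counts$f_R <- 0L
  if (!"f_Q" %in% names(counts)) counts$f_Q <- 0L
  counts
}

#' Compute all per-attribute Kano indices
#'
#' From a per-attribute frequency table, computes the Better and Worse
#' coefficients, total satisfaction index, category strength, importance
#' degree and the modal category assignment. All values are kept at full
#' precision (fractions); use [round_half_up()] or [write_results()] for
#' report formatting.
#'
#' @param counts Data frame with columns `attribute`, `f_M`, `f_O`, `f_A`,
#'   `f_I` (and optionally `f_R`, `f_Q`), e.g. from [kano_tabulate()] or
#'   [sports_demand_counts()].
#' @param worse_mode Passed to [worse_index()].
#' @param tie_break Passed to [classify_attribute()].
#' @return A tibble: `attribute`, `n_classifiable`, `better`, `worse`,
#'   `total_satisfaction`, `category_strength`, `importance_degree`,
#'   `category`.
#' @examples
#' kano_indices(sports_demand_counts())
#' @export
kano_indices <- function(counts, worse_mode = c("berger", "attractive_must"),
                         tie_break = c("M", "O", "A", "I")) {
  worse_mode <- match.arg(worse_mode)
  counts <- .as_counts_df(counts)
  with(counts, tibble::tibble(
    attribute = attribute,
    n_classifiable = f_M + f_O + f_A + f_I,
    better = better_index(f_M, f_O, f_A, f_I),
    worse = worse_index(f_M, f_O, f_A, f_I, mode = worse_mode),
    total_satisfaction = total_satisfaction(f_M, f_O, f_A, f_I),
    category_strength = category_strength(f_M, f_O, f_A, f_I),
    importance_degree = importance_degree(f_M, f_O, f_A, f_I),
    category = classify_attribute(f_M, f_O, f_A, f_I, tie_break = tie_break)
  ))
}

#' Survey-level Kano summary
#'
#' Runs the full attribute-level analysis and aggregates it: per-attribute
#' indices joined to the dimension manifest, the unweighted mean importance
#' degree (over unrounded values), the attributes strictly above that mean,
#' and the census of assigned categories.
#'
#' @param x A [kano_survey()] object, or a per-attribute counts table as
#'   accepted by [kano_indices()].
#' @param manifest Optional attribute manifest (used when `x` is a counts
#'   table); joined onto the indices by `attribute`.
#' @inheritParams kano_indices
#' @inheritParams classify_response
#' @return An object of class `kano_summary`: a list with elements
#'   `indices` (tibble), `mean_importance`, `above_average_ids`,
#'   `category_census` (named integer vector over M, O, A, I, R, Q),
#'   `worse_mode` and `tie_break`.
#' @examples
#' s <- summarize_survey(sports_demand_counts(),
#'                       manifest = sports_demand_attributes())
#' s
#' @export
summarize_survey <- function(x, manifest = NULL,
                             worse_mode = c("berger", "attractive_must"),
                             tie_break = c("M", "O", "A", "I"),
                             table = kano_evaluation_table()) {
  worse_mode <- match.arg(worse_mode)
  if (inherits(x, "kano_survey")) {
    manifest <- manifest %||% x$manifest
    counts <- kano_tabulate(x, table = table)
  } else {
    counts <- .as_counts_df(x)
  }
  idx <- kano_indices(counts, worse_mode = worse_mode, tie_break = tie_break)
  if (!is.null(manifest)) {
    manifest <- tibble::as_tibble(manifest)
    keep <- intersect(c("attribute", "dimension", "dimension_name"), names(manifest))
    idx <- dplyr::left_join(idx, manifest[keep], by = "attribute")
  }
  mean_id <- mean(idx$importance_degree)
  census <- table(factor(idx$category, levels = kano_categories()))
  structure(list(
    indices = idx,
    mean_importance = mean_id,
    above_average_ids = idx$attribute[idx$importance_degree > mean_id],
    category_census = stats::setNames(as.integer(census), kano_categories()),
    worse_mode = worse_mode,
    tie_break = tie_break
  ), class = "kano_summary")
}

#' @export
print.kano_summary <- function(x, digits = 2, ...) {
  cat("<kano_summary> ", nrow(x$indices), " attributes\n", sep = "")
  census <- x$category_census[x$category_census > 0]
  cat("  category census: ",
      paste(names(census), census, sep = ":", collapse = "  "), "\n", sep = "")
  cat("  mean importance degree: ", round_half_up(x$mean_importance, digits),
      " (", length(x$above_average_ids), " attributes above the mean)\n", sep = "")
  print(x$indices, ...)
  invisible(x)
}

#' Audit recomputed indices against a published reference table
#'
#' Rounds the recomputed indices the way the reference table is printed
#' (Better/Worse as signed percentages, the other three as plain values,
#' half-up to `digits` decimals) and reports cell-by-cell agreement. Cells
#' that disagree indicate values in the reference that are arithmetically
#' inconsistent with the underlying frequency table; the recomputed value is
#' the formula-consistent one.
#'
#' @param indices Output of [kano_indices()] or the `indices` element of a
#'   [summarize_survey()] result.
#' @param reference Data frame with columns `attribute`, `better`, `worse`
#'   (in percent), `total_satisfaction`, `category_strength`,
#'   `importance_degree`; defaults to the bundled case-study table
#'   [sports_demand_reference()].
#' @param digits Decimal places of the reference (default 2).
#' @return A tibble with one row per attribute x quantity: `attribute`,
#'   `quantity`, `computed`, `reference`, `match`.
#' @examples
#' audit <- compare_reference(kano_indices(sports_demand_counts()))
#' subset(audit, !match)
#' @export
compare_reference <- function(indices, reference = sports_demand_reference(),
                              digits = 2) {
  reference <- tibble::as_tibble(reference)
  quantities <- c("better", "worse", "total_satisfaction",
                  "category_strength", "importance_degree")
  stopifnot(all(c("attribute", quantities) %in% names(reference)))
  computed <- tibble::tibble(
    attribute = indices$attribute,
    better = round_half_up(indices$better * 100, digits),
    worse = round_half_up(indices$worse * 100, digits),
    total_satisfaction = round_half_up(indices$total_satisfaction, digits),
    category_strength = round_half_up(indices$category_strength, digits),
    importance_degree = round_half_up(indices$importance_degree, digits)
  )
  long <- function(df, value_name) {
    tidyr::pivot_longer(df, dplyr::all_of(quantities),
                        names_to = "quantity", values_to = value_name)
  }
  out <- dplyr::inner_join(
    long(computed, "computed"),
    long(reference[c("attribute", quantities)], "reference"),
    by = c("attribute", "quantity")
  )
  out$match <- abs(out$computed - out$reference) < 10^(-digits) / 2
  out
}
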