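#' Construct a Kano survey dataset
#'
#' Bundles a wide respondent table (one row per respondent; per attribute `X`
#' two columns `X_func` and `X_dysf` holding answer codes 1-5 or `NA`) with
#' an attribute manifest mapping each attribute to its service dimension.
#'
#' @param data Data frame with a `respondent_id` column followed by
#'   `<attribute>_func` / `<attribute>_dysf` column pairs.
#' @param manifest Data frame with columns `attribute`, `dimension` and
#'   optionally `wording` and `dimension_name`. If `NULL`, a minimal manifest
#'   is derived from the column names (dimension = leading letter of the
#'   attribute id).
#' @return An object of class `kano_survey`: a list with elements `data`
#'   (tibble) and `manifest` (tibble).
#' @examples
#' d <- data.frame(respondent_id = 1:2,
#'                 A1_func = c(1, 2), A1_dysf = c(5, 5))
#' kano_survey(d)
#' @export
kano_survey <- function(data, manifest = NULL) {
  data <- tibble::as_tibble(data)
  if (!"respondent_id" %in% names(data)) {
    stop("`data` must contain a `respondent_id` column", call. = FALSE)
  }
  if (anyDuplicated(data$respondent_id)) {
    dup <- unique(data$respondent_id[duplicated(data$respondent_id)])
    stop("duplicate respondent id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  cols <- setdiff(names(data), "respondent_id")
  bad <- cols[!grepl("_(func|dysf)$", cols)]
  if (length(bad)) {
    stop("unrecognised data column(s): ", paste(bad, collapse = ", "),
         " (expected `<attribute>_func` / `<attribute>_dysf`)", call. = FALSE)
  }
  attrs <- unique(sub("_(func|dysf)$", "", cols))
  missing_cols <- c(
    setdiff(paste0(attrs, "_func"), cols),
    setdiff(paste0(attrs, "_dysf"), cols)
  )
  if (length(missing_cols)) {
    stop("unpaired attribute column(s); missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cl in cols) {
    codes <- tryCatch(
      normalize_answers(data[[cl]]),
      error = function(e) {
        stop("column `", cl, "`: ", conditionMessage(e), call. = FALSE)
      }
    )
    data[[cl]] <- codes
  }
  if (is.null(manifest)) {
    manifest <- tibble::tibble(
      attribute = attrs,
      wording = attrs,
      dimension = substr(attrs, 1, 1),
      dimension_name = substr(attrs, 1, 1)
    )
  } else {
    manifest <- tibble::as_tibble(manifest)
    if (!all(c("attribute", "dimension") %in% names(manifest))) {
      stop("`manifest` must have columns `attribute` and `dimension`", call. = FALSE)
    }
    if (anyDuplicated(manifest$attribute)) {
      stop("duplicate attribute ids in manifest", call. = FALSE)
    }
    if (!"wording" %in% names(manifest)) manifest$wording <- manifest$attribute
    if (!"dimension_name" %in% names(manifest)) {
      manifest$dimension_name <- manifest$dimension
    }
    unknown <- setdiff(attrs, manifest$attribute)
    if (length(unknown)) {
      stop("data column(s) for attribute(s) absent from manifest: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    manifest <- manifest[manifest$attribute %in% attrs, ]
  }
  structure(list(data = data, manifest = manifest), class = "kano_survey")
}

#' @export
print.kano_survey <- function(x, ...) {
  cat("<kano_survey> ", nrow(x$data), " respondents x ",
      nrow(x$manifest), " attributes (",
      length(unique(x$manifest$dimension)), " dimensions)\n", sep = "")
  n_miss <- sum(is.na(as.matrix(x$data[setdiff(names(x$data), "respondent_id")])))
  if (n_miss > 0) cat("  ", n_miss, " missing answer cells\n", sep = "")
  invisible(x)
}

#' Attribute ids of a survey
#' @param survey A [kano_survey()] object.
#' @return Character vector of attribute ids, in manifest order.
#' @export
survey_attributes <- function(survey) {
  stopifnot(inherits(survey, "kano_survey"))
  survey$manifest$attribute
}

#' Extract one polarity of a survey as an item-response matrix
#'
#' Pulls the functional or dysfunctional answer bank as a respondents x
#' items integer matrix (columns named by attribute id), the input format of
#' the reliability statistics. Rows with any missing answer are dropped
#' (listwise deletion) when `listwise = TRUE`.
#'
#' @param survey A [kano_survey()] object.
#' @param polarity `"functional"` or `"dysfunctional"`.
#' @param listwise Drop respondents with any missing item (default `TRUE`).
#' @return Integer matrix with attribute ids as column names and a
#'   `dimension` attribute giving each item's dimension label.
#' @export
item_matrix <- function(survey, polarity = c("functional", "dysfunctional"),
                        listwise = TRUE) {
  stopifnot(inherits(survey, "kano_survey"))
  polarity <- match.arg(polarity)
  suffix <- if (polarity == "functional") "_func" else "_dysf"
  attrs <- survey_attributes(survey)
  m <- as.matrix(survey$data[paste0(attrs, suffix)])
  colnames(m) <- attrs
  rownames(m) <- as.character(survey$data$respondent_id)
  if (listwise) m <- m[stats::complete.cases(m), , drop = FALSE]
  attr(m, "dimension") <- stats::setNames(survey$manifest$dimension, attrs)
  m
}
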