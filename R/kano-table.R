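#' The five-level Kano answer scale
#'
#' Both members of a Kano question pair are answered on the same five-level
#' scale, coded 1-5 in the order the options are presented to respondents:
#' 1 = "I like it that way", 2 = "It must be that way", 3 = "I am neutral",
#' 4 = "I can live with it", 5 = "I dislike it that way". The ordering is
#' fixed and used only for validation, never for arithmetic.
#'
#' @return A tibble with columns `code` (integer 1-5) and `label`.
#' @examples
#' answer_levels()
#' @export
answer_levels <- function() {
  tibble::tibble(
    code = 1:5,
    label = c(
      "I like it that way",
      "It must be that way",
      "I am neutral",
      "I can live with it",
      "I dislike it that way"
    )
  )
}

# Wording variants seen on questionnaires; all map onto the same five codes.
.answer_synonyms <- c(
  "i like it that way" = 1L, "i like that" = 1L,
  "it must be that way" = 2L, "it must be that" = 2L,
  "i am neutral" = 3L, "neutral" = 3L,
  "i can live with it" = 4L, "i can tolerate that" = 4L,
  "i dislike it that way" = 5L, "i do not like that" = 5L,
  "i dislike that" = 5L
)

#' Normalise answer values to integer codes 1-5
#'
#' Accepts integer codes, numeric strings, or any of the recognised English
#' option wordings (e.g. both "I like that" and "I like it that way" mean
#' code 1). Empty strings and `NA` become `NA` (a missing answer); anything
#' else is an error naming the offending value.
#'
#' @param x Vector of answers: integers, numeric strings or option labels.
#' @return Integer vector of codes in 1-5, with `NA` for missing.
#' @examples
#' normalize_answers(c("1", "I like that", "I dislike it that way", NA))
#' @export
normalize_answers <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    out <- as.integer(x)
    bad <- !is.na(out) & (out != x | out < 1L | out > 5L)
    if (any(bad)) {
      stop("invalid answer value(s): ", paste(unique(x[bad]), collapse = ", "),
           " (expected integer codes 1-5 or option labels)", call. = FALSE)
    }
    return(out)
  }
  x <- trimws(as.character(x))
  out <- rep(NA_integer_, length(x))
  missing <- is.na(x) | x == ""
  numeric_like <- !missing & grepl("^[0-9]+$", x)
  out[numeric_like] <- as.integer(x[numeric_like])
  labelled <- !missing & !numeric_like
  out[labelled] <- .answer_synonyms[tolower(x[labelled])]
  bad <- !missing & (is.na(out) | out < 1L | out > 5L)
  if (any(bad)) {
    stop("invalid answer value(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected integer codes 1-5 or option labels)", call. = FALSE)
  }
  out
}

#' Kano category labels
#'
#' The closed set of six Kano categories: M (must-be), O (one-dimensional),
#' A (attractive), I (indifferent), R (reverse) and Q (questionable).
#'
#' @return Character vector of the six labels.
#' @export
kano_categories <- function() c("M", "O", "A", "I", "R", "Q")

#' The 5x5 Kano evaluation table
#'
#' Maps a (functional, dysfunctional) answer pair to a Kano category. Rows
#' index the functional answer (1-5), columns the dysfunctional answer. The
#' default is the standard table: agreement corners (1,1) and (5,5) are
#' questionable (Q); liking the presence while tolerating the absence is
#' attractive (A); (1,5) is the single one-dimensional cell (O); disliking
#' the absence while merely tolerating the presence is must-be (M); the
#' central 3x3 block is indifferent (I); preferring the absence is reverse
#' (R). The table is data, not code: a variant grid can be passed to
#' [classify_response()] and downstream tabulation.
#'
#' @return A 5x5 character matrix with dimnames `functional`/`dysfunctional`.
#' @examples
#' kano_evaluation_table()
#' @export
kano_evaluation_table <- function() {
  grid <- matrix(
    c(
      "Q", "A", "A", "A", "O",
      "R", "I", "I", "I", "M",
      "R", "I", "I", "I", "M",
      "R", "I", "I", "I", "M",
      "R", "R", "R", "R", "Q"
    ),
    nrow = 5, byrow = TRUE,
    dimnames = list(functional = 1:5, dysfunctional = 1:5)
  )
  grid
}

.check_evaluation_table <- function(table) {
  if (!is.matrix(table) || !identical(dim(table), c(5L, 5L)) ||
      !all(table %in% kano_categories())) {
    stop("`table` must be a 5x5 matrix of Kano category labels", call. = FALSE)
  }
  invisible(table)
}

#' Classify one or more functional/dysfunctional answer pairs
#'
#' Looks up each (functional, dysfunctional) pair in the Kano evaluation
#' table. Pure and total over the 25-cell domain; pairs with a missing
#' answer on either side classify as `NA`.
#'
#' @param functional,dysfunctional Answer codes 1-5 (or labels; normalised
#'   via [normalize_answers()]). Recycled to a common length.
#' @param table Evaluation grid, by default [kano_evaluation_table()].
#' @return Character vector of Kano category labels.
#' @examples
#' classify_response(1, 5) # one-dimensional
#' classify_response(c(1, 3, 5), c(1, 3, 2))
#' @export
classify_response <- function(functional, dysfunctional,
                              table = kano_evaluation_table()) {
  .check_evaluation_table(table)
  f <- normalize_answers(functional)
  d <- normalize_answers(dysfunctional)
  n <- max(length(f), length(d))
  f <- rep_len(f, n)
  d <- rep_len(d, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(f) & !is.na(d)
  out[ok] <- table[cbind(f[ok], d[ok])]
  out
}

#' Answer pairs mapping to a Kano category
#'
#' The inverse image of the evaluation table: all (functional, dysfunctional)
#' cells that classify to the given category. The six inverse images are
#' pairwise disjoint and their union is the full 25-cell domain.
#'
#' @param category One of `"M"`, `"O"`, `"A"`, `"I"`, `"R"`, `"Q"`.
#' @inheritParams classify_response
#' @return A tibble with integer columns `functional` and `dysfunctional`.
#' @examples
#' valid_pairs_for("O") # the single (1, 5) cell
#' nrow(valid_pairs_for("I")) # 9
#' @export
valid_pairs_for <- function(category, table = kano_evaluation_table()) {
  .check_evaluation_table(table)
  if (length(category) != 1L || !category %in% kano_categories()) {
    stop("`category` must be one of ", paste(kano_categories(), collapse = ", "),
         call. = FALSE)
  }
  idx <- which(table == category, arr.ind = TRUE)
  tibble::tibble(
    functional = as.integer(idx[, 1]),
    dysfunctional = as.integer(idx[, 2])
  )
}
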