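.as_item_matrix <- function(x, min_items = 2L, min_resp = 3L) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (ncol(m) < min_items) {
    stop("need at least ", min_items, " items", call. = FALSE)
  }
  if (nrow(m) < min_resp) {
    stop("need at least ", min_resp, " complete respondents", call. = FALSE)
  }
  m
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a set of items:
#' alpha = k/(k-1) * (1 - sum of item variances / variance of the total
#' score). Variances use the sample (n-1) denominator. Rows with any
#' missing item are dropped (listwise deletion). Alpha is at most 1; it can
#' be negative for incoherent item sets.
#'
#' @param x Respondents x items numeric matrix or data frame (k >= 2 items,
#'   >= 3 complete respondents).
#' @return Scalar alpha.
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 5))
#' cronbach_alpha(m)
#' @export
cronbach_alpha <- function(x) {
  m <- .as_item_matrix(x)
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) {
    stop("degenerate responses: total-score variance is zero", call. = FALSE)
  }
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO: the ratio of the summed squared off-diagonal correlations to
#' that sum plus the summed squared off-diagonal partial correlations, the
#' partials taken from the anti-image of the correlation matrix. Values near
#' 1 indicate compact correlation structure suitable for factor analysis;
#' values near 0.5 indicate diffuse correlations. With exactly two items the
#' partial correlation equals the correlation and KMO is 0.5 by identity.
#'
#' @inheritParams cronbach_alpha
#' @return Scalar in \[0, 1\].
#' @export
kmo_overall <- function(x) {
  m <- .as_item_matrix(x)
  r <- stats::cor(m)
  inv <- tryCatch(solve(r), error = function(e) {
    stop("correlation matrix is singular; remove redundant items", call. = FALSE)
  })
  d <- 1 / sqrt(diag(inv))
  partial <- -inv * outer(d, d) # anti-image partial correlations
  off <- upper.tri(r)
  sum(r[off]^2) / (sum(r[off]^2) + sum(partial[off]^2))
}

#' Bartlett's test of sphericity
#'
#' Tests whether the item correlation matrix is the identity (no common
#' structure): chi-square = -(n - 1 - (2k + 5)/6) * log det(R) on
#' k(k-1)/2 degrees of freedom, with the p-value from the upper tail.
#'
#' @inheritParams cronbach_alpha
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
bartlett_sphericity <- function(x) {
  m <- .as_item_matrix(x)
  n <- nrow(m)
  k <- ncol(m)
  if (n <= k) stop("need more respondents than items", call. = FALSE)
  r <- stats::cor(m)
  det_r <- det(r)
  if (det_r <= 0) {
    # collinear items: the statistic diverges
    return(list(statistic = Inf, df = k * (k - 1) / 2, p_value = 0))
  }
  stat <- -(n - 1 - (2 * k + 5) / 6) * log(det_r)
  df <- k * (k - 1) / 2
  list(statistic = stat, df = df, p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Reliability and factorability report for a Kano survey
#'
#' Computes Cronbach's alpha per dimension and over all items, separately
#' for the functional and dysfunctional question banks, plus the overall
#' KMO measure and Bartlett's sphericity test on the combined item matrix
#' (both banks side by side). Respondents with missing answers are dropped
#' listwise within each item set. Pearson correlations treat the ordinal
#' codes as numeric, the common practice for five-level Likert items.
#'
#' @param survey A [kano_survey()] object.
#' @return A list of class `kano_reliability`: `alpha` (tibble with columns
#'   `dimension`, `polarity`, `n_items`, `alpha`; dimension `"overall"`
#'   pools all items of a polarity), `kmo`, `bartlett` and `n_respondents`.
#' @examples
#' spec <- tibble::tibble(item = c("A1", "A2", "B1", "B2"),
#'                        dimension = c("A", "A", "B", "B"),
#'                        loading = 0.8)
#' m <- generate_likert_factor(spec, n = 200, seed = 7)
#' cronbach_alpha(m[, 1:2])
#' @export
reliability_report <- function(survey) {
  stopifnot(inherits(survey, "kano_survey"))
  banks <- list(
    functional = item_matrix(survey, "functional", listwise = FALSE),
    dysfunctional = item_matrix(survey, "dysfunctional", listwise = FALSE)
  )
  rows <- list()
  for (pol in names(banks)) {
    m <- banks[[pol]]
    dims <- attr(m, "dimension")
    for (d in unique(dims)) {
      items <- names(dims)[dims == d]
      a <- if (length(items) >= 2) {
        tryCatch(cronbach_alpha(m[, items, drop = FALSE]),
                 error = function(e) NA_real_)
      } else NA_real_
      rows[[length(rows) + 1]] <- tibble::tibble(
        dimension = d, polarity = pol, n_items = length(items), alpha = a
      )
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      dimension = "overall", polarity = pol, n_items = ncol(m),
      alpha = tryCatch(cronbach_alpha(m), error = function(e) NA_real_)
    )
  }
  # banks share row order, so a plain cbind aligns respondents
  combined <- cbind(
    `colnames<-`(banks$functional, paste0(colnames(banks$functional), "_func")),
    `colnames<-`(banks$dysfunctional, paste0(colnames(banks$dysfunctional), "_dysf"))
  )
  combined <- combined[stats::complete.cases(combined), , drop = FALSE]
  structure(list(
    alpha = dplyr::bind_rows(rows),
    kmo = tryCatch(kmo_overall(combined), error = function(e) NA_real_),
    bartlett = tryCatch(bartlett_sphericity(combined),
                        error = function(e) list(statistic = NA_real_,
                                                 df = NA_real_,
                                                 p_value = NA_real_)),
    n_respondents = nrow(combined)
  ), class = "kano_reliability")
}

#' @export
print.kano_reliability <- function(x, ...) {
  cat("<kano_reliability> ", x$n_respondents, " complete respondents\n", sep = "")
  cat("  KMO: ", round_half_up(x$kmo, 3),
      "; Bartlett chi-sq ", round_half_up(x$bartlett$statistic, 1),
      " on ", x$bartlett$df, " df, p ",
      format.pval(x$bartlett$p_value, digits = 3), "\n", sep = "")
  print(x$alpha, n = Inf, ...)
  invisible(x)
}
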