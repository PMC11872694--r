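.draw_pairs_for <- function(category, n, table, pair_choice) {
  cells <- valid_pairs_for(category, table = table)
  idx <- switch(pair_choice,
    uniform = sample.int(nrow(cells), n, replace = TRUE),
    canonical = rep(1L, n)
  )
  cells[idx, , drop = FALSE]
}

#' Generate respondents realising exact per-attribute category counts
#'
#' Inverse of [kano_tabulate()]: for each attribute, emits exactly the
#' requested number of answer pairs per Kano category, assigning categories
#' to respondents in seeded random order and drawing each pair uniformly
#' from the cells of the evaluation table that classify to that category
#' (`pair_choice = "uniform"`, the default) or from a fixed canonical cell
#' per category (`"canonical"`). Tabulating the generated survey returns
#' the input counts exactly, for any seed. Respondents are independent
#' across attributes: only the per-attribute category frequencies — the
#' sufficient statistic of all downstream indices — are controlled.
#'
#' @param counts Data frame with columns `attribute`, `f_M`, `f_O`, `f_A`,
#'   `f_I` and optionally `f_R`, `f_Q`; every row must sum to the same
#'   respondent total.
#' @param seed Integer seed (mandatory; no hidden global RNG state is used).
#' @param manifest Optional attribute manifest passed to [kano_survey()].
#' @param pair_choice `"uniform"` or `"canonical"`.
#' @inheritParams classify_response
#' @return A [kano_survey()] object with `n` respondents.
#' @examples
#' svy <- generate_from_counts(sports_demand_counts(), seed = 1)
#' all(kano_tabulate(svy)$f_M == sports_demand_counts()$f_M)
#' @export
generate_from_counts <- function(counts, seed, manifest = NULL,
                                 pair_choice = c("uniform", "canonical"),
                                 table = kano_evaluation_table()) {
  pair_choice <- match.arg(pair_choice)
  counts <- .as_counts_df(counts)
  count_cols <- paste0("f_", kano_categories())
  totals <- rowSums(counts[count_cols])
  if (length(unique(totals)) != 1L) {
    stop("per-attribute counts must sum to the same respondent total; got ",
         paste(unique(totals), collapse = ", "), call. = FALSE)
  }
  n <- totals[[1]]
  if (n < 1) stop("respondent total must be at least 1", call. = FALSE)
  data <- tibble::tibble(respondent_id = seq_len(n))
  withr::with_seed(seed, {
    for (i in seq_len(nrow(counts))) {
      cats <- rep(kano_categories(), times = as.integer(counts[i, count_cols]))
      cats <- sample(cats) # random assignment of categories to respondents
      func <- integer(n)
      dysf <- integer(n)
      for (cat in unique(cats)) {
        at <- which(cats == cat)
        cells <- .draw_pairs_for(cat, length(at), table, pair_choice)
        func[at] <- cells$functional
        dysf[at] <- cells$dysfunctional
      }
      data[[paste0(counts$attribute[i], "_func")]] <- func
      data[[paste0(counts$attribute[i], "_dysf")]] <- dysf
    }
  })
  kano_survey(data, manifest = manifest)
}

#' Generate respondents from per-attribute category mixtures
#'
#' Each respondent x attribute cell draws a Kano category from the
#' attribute's probability vector over (M, O, A, I, R, Q), then a uniformly
#' chosen answer pair from that category's cells. Used for recovery and
#' robustness experiments where sampling noise in the category frequencies
#' matters.
#'
#' @param probs Data frame with columns `attribute` and `p_M`, `p_O`,
#'   `p_A`, `p_I` (optionally `p_R`, `p_Q`); each row a probability vector
#'   summing to 1.
#' @param n Number of respondents.
#' @inheritParams generate_from_counts
#' @return A [kano_survey()] object.
#' @examples
#' probs <- tibble::tibble(attribute = "A1", p_M = 0.5, p_O = 0.2,
#'                         p_A = 0.2, p_I = 0.1)
#' svy <- generate_mixture(probs, n = 100, seed = 42)
#' @export
generate_mixture <- function(probs, n, seed, manifest = NULL,
                             pair_choice = c("uniform", "canonical"),
                             table = kano_evaluation_table()) {
  pair_choice <- match.arg(pair_choice)
  probs <- tibble::as_tibble(probs)
  if (!"attribute" %in% names(probs)) {
    stop("`probs` must have an `attribute` column", call. = FALSE)
  }
  prob_cols <- paste0("p_", kano_categories())
  for (pc in prob_cols) if (!pc %in% names(probs)) probs[[pc]] <- 0
  pm <- as.matrix(probs[prob_cols])
  if (any(pm < 0) || any(abs(rowSums(pm) - 1) > 1e-8)) {
    stop("each attribute's probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  data <- tibble::tibble(respondent_id = seq_len(n))
  withr::with_seed(seed, {
    for (i in seq_len(nrow(probs))) {
      cats <- sample(kano_categories(), n, replace = TRUE, prob = pm[i, ])
      func <- integer(n)
      dysf <- integer(n)
      for (cat in unique(cats)) {
        at <- which(cats == cat)
        cells <- .draw_pairs_for(cat, length(at), table, pair_choice)
        func[at] <- cells$functional
        dysf[at] <- cells$dysfunctional
      }
      data[[paste0(probs$attribute[i], "_func")]] <- func
      data[[paste0(probs$attribute[i], "_dysf")]] <- dysf
    }
  })
  kano_survey(data, manifest = manifest)
}

#' Generate correlated five-level Likert items from a latent factor model
#'
#' Simulates the within-dimension correlation structure that reliability
#' statistics measure: each dimension has one standard-normal common factor;
#' item j in that dimension is loading_j * factor + sqrt(1 - loading_j^2) *
#' noise, discretised into codes 1-5 at fixed cut points. With loadings
#' near 1 the items are near-duplicates (alpha -> 1); with loadings 0 they
#' are independent (alpha near 0).
#'
#' @param items Data frame with columns `item`, `dimension` and `loading`
#'   (each loading in \[0, 1\]).
#' @param n Number of respondents.
#' @param seed Integer seed.
#' @param cutpoints Strictly increasing numeric vector of length 4 cutting
#'   the latent scale into 5 ordinal levels (default symmetric
#'   `c(-1.5, -0.5, 0.5, 1.5)`).
#' @return Respondents x items integer matrix of codes 1-5, columns named
#'   by `item`, with a `dimension` attribute.
#' @examples
#' spec <- tibble::tibble(item = paste0("x", 1:4), dimension = "A", loading = 0.9)
#' m <- generate_likert_factor(spec, n = 500, seed = 1)
#' cronbach_alpha(m)
#' @export
generate_likert_factor <- function(items, n, seed,
                                   cutpoints = c(-1.5, -0.5, 0.5, 1.5)) {
  items <- tibble::as_tibble(items)
  stopifnot(all(c("item", "dimension", "loading") %in% names(items)))
  if (any(items$loading < 0 | items$loading > 1)) {
    stop("loadings must lie in [0, 1]", call. = FALSE)
  }
  if (length(cutpoints) != 4 || any(diff(cutpoints) <= 0)) {
    stop("`cutpoints` must be 4 strictly increasing values", call. = FALSE)
  }
  withr::with_seed(seed, {
    factors <- matrix(stats::rnorm(n * length(unique(items$dimension))),
                      nrow = n,
                      dimnames = list(NULL, unique(items$dimension)))
    m <- matrix(NA_integer_, nrow = n, ncol = nrow(items),
                dimnames = list(NULL, items$item))
    for (j in seq_len(nrow(items))) {
      lam <- items$loading[j]
      latent <- lam * factors[, items$dimension[j]] +
        sqrt(1 - lam^2) * stats::rnorm(n)
      m[, j] <- as.integer(findInterval(latent, cutpoints) + 1L)
    }
  })
  attr(m, "dimension") <- stats::setNames(items$dimension, items$item)
  m
}
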