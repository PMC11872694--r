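#' Bundled case study: public sports service demand of older adults
#'
#' The package ships the published aggregate data of a Kano-model demand
#' survey of N = 436 older adults, covering 23 public sports service
#' attributes in six dimensions (A physical monitoring, B sports activities,
#' C sports information, D fitness facilities, E fitness guidance, F fitness
#' organization). Three plain-text tables are included:
#'
#' * `sports_demand_attributes()` — the attribute manifest (id, wording,
#'   dimension);
#' * `sports_demand_counts()` — per-attribute Kano category frequencies
#'   (`f_M`, `f_O`, `f_A`, `f_I`, `f_R`, `f_Q`); every row sums to 436 over
#'   M/O/A/I, i.e. no reverse or questionable responses remained;
#' * `sports_demand_reference()` — the indices as published (Better and
#'   Worse in signed percent, total satisfaction index, category strength
#'   and importance degree as plain two-decimal values, plus the assigned
#'   category), used by [compare_reference()] to audit recomputation. A
#'   handful of its Better/Worse cells are arithmetically inconsistent with
#'   the counts table; the package reproduces the formula-consistent values
#'   and flags the rest.
#'
#' @return A tibble (see per-function details above).
#' @name sports_demand
NULL

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "kanodemand", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname sports_demand
#' @export
sports_demand_attributes <- function() .extdata("sports_demand_attributes.csv")

#' @rdname sports_demand
#' @export
sports_demand_counts <- function() {
  out <- .extdata("sports_demand_counts.csv")
  out[-1] <- lapply(out[-1], as.integer)
  out
}

#' @rdname sports_demand
#' @export
sports_demand_reference <- function() .extdata("sports_demand_reference.csv")
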