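# random valid per-attribute count tables for property tests
random_counts <- function(n_attr, n_resp = 200, with_rq = FALSE) {
  cats <- if (with_rq) c("M", "O", "A", "I", "R", "Q") else c("M", "O", "A", "I")
  rows <- lapply(seq_len(n_attr), function(i) {
    repeat {
      draw <- as.integer(stats::rmultinom(1, n_resp, prob = stats::runif(length(cats))))
      if (sum(draw[1:4]) >= 1) break # need a classifiable response
    }
    counts <- stats::setNames(as.list(draw), paste0("f_", cats))
    tibble::as_tibble_row(c(list(attribute = paste0("X", i)), counts))
  })
  out <- dplyr::bind_rows(rows)
  if (!with_rq) {
    out$f_R <- 0L
    out$f_Q <- 0L
  }
  out
}

# the 13 published index cells known to disagree with the frequency table
known_discrepant_cells <- function() {
  tibble::tribble(
    ~attribute, ~quantity,
    "A3", "better", "A3", "worse",
    "B1", "worse",
    "C1", "better",
    "C4", "better", "C4", "worse",
    "C5", "better", "C5", "worse",
    "D1", "better",
    "D2", "better",
    "D5", "worse",
    "E3", "better",
    "E4", "better"
  )
}
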