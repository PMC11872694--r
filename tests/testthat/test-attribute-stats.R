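test_that("tabulate_pairs counts each pair in exactly one bucket", {
  expect_equal(
    tabulate_pairs(1, 5),
    c(f_M = 0L, f_O = 1L, f_A = 0L, f_I = 0L, f_R = 0L, f_Q = 0L)
  )
  grid <- expand.grid(functional = 1:5, dysfunctional = 1:5)
  expect_equal(
    tabulate_pairs(grid$functional, grid$dysfunctional),
    c(f_M = 3L, f_O = 1L, f_A = 3L, f_I = 9L, f_R = 7L, f_Q = 2L)
  )
  # missing pairs are excluded; counts sum to the complete pairs
  counts <- tabulate_pairs(c(1, NA, 2), c(5, 5, NA))
  expect_equal(sum(counts), 1L)
  expect_error(tabulate_pairs(NA, NA), "no classifiable")
})

test_that("conservation: bucket counts sum to input size", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      f <- sample(1:5, 60, replace = TRUE)
      d <- sample(1:5, 60, replace = TRUE)
      expect_equal(sum(tabulate_pairs(f, d)), 60L)
    }
  })
})

test_that("index formulas reproduce the case-study cells at full precision", {
  # frozen from the bundled counts: A1 (153,114,74,95), F3 (101,150,105,80)
  expect_equal(better_index(153, 114, 74, 95), 188 / 436)
  expect_equal(round_half_up(100 * better_index(101, 150, 105, 80), 2), 58.49)
  expect_equal(worse_index(118, 152, 71, 95), -270 / 436)
  expect_equal(round_half_up(100 * worse_index(118, 152, 71, 95), 2), -61.93)
  # the two Worse conventions disagree where f_A != f_O
  expect_equal(worse_index(153, 114, 74, 95, mode = "attractive_must"), -227 / 436)
  expect_equal(worse_index(153, 114, 74, 95, mode = "berger"), -267 / 436)
  expect_equal(importance_degree(179, 161, 61, 35), 1439 / 436)
  expect_equal(total_satisfaction(166, 159, 78, 33), 403 / 436)
  expect_equal(category_strength(95, 83, 154, 104), 59 / 436)
})

test_that("index endpoints and degenerate counts behave", {
  expect_equal(better_index(0, 0, 0, 10), 0)
  expect_equal(worse_index(0, 0, 0, 10), 0)
  expect_equal(importance_degree(0, 0, 0, 10), 0)
  expect_equal(importance_degree(10, 0, 0, 0), 5)
  expect_equal(total_satisfaction(0, 0, 0, 10), 0)
  expect_equal(category_strength(7, 7, 7, 2), 0)
  expect_error(better_index(0, 0, 0, 0), "classifiable")
  expect_error(worse_index(1, 1, 1, 1, mode = "nope"))
})

test_that("modal classification matches brute force and honours tie order", {
  expect_equal(classify_attribute(105, 87, 134, 110), "A")
  expect_equal(classify_attribute(96, 73, 74, 193), "I")
  expect_equal(classify_attribute(10, 10, 0, 0), "M")
  expect_equal(classify_attribute(10, 10, 0, 0, tie_break = c("O", "M", "A", "I")), "O")
  withr::with_seed(5, {
    for (rep in 1:50) {
      x <- as.integer(stats::rmultinom(1, 100, prob = rep(0.25, 4)))
      if (sum(x) == 0) next
      got <- classify_attribute(x[1], x[2], x[3], x[4])
      brute <- c("M", "O", "A", "I")[which(x == max(x))]
      expect_true(got %in% brute)
      # among the tied maxima the default order prefers the earliest
      expect_equal(got, intersect(c("M", "O", "A", "I"), brute)[1])
    }
  })
  expect_error(classify_attribute(0, 0, 0, 0), "classifiable")
})

test_that("index bounds and the TSI/ID sandwich hold on random counts", {
  withr::with_seed(21, {
    tab <- random_counts(200)
    idx <- kano_indices(tab)
    expect_true(all(idx$better >= 0 & idx$better <= 1))
    expect_true(all(idx$worse >= -1 & idx$worse <= 0))
    expect_true(all(idx$total_satisfaction >= 0 & idx$total_satisfaction <= 1))
    expect_true(all(idx$category_strength >= 0 & idx$category_strength <= 1))
    expect_true(all(idx$importance_degree >= 0 & idx$importance_degree <= 5))
    expect_true(all(idx$total_satisfaction <= idx$importance_degree + 1e-12))
    expect_true(all(idx$importance_degree <= 5 * idx$total_satisfaction + 1e-12))
  })
})

test_that("survey summary aggregates the bundled case study correctly", {
  s <- summarize_survey(sports_demand_counts(),
                        manifest = sports_demand_attributes())
  expect_equal(s$category_census[c("M", "O", "A", "I")],
               c(M = 9L, O = 2L, A = 3L, I = 9L))
  expect_equal(round_half_up(s$mean_importance, 2), 2.25)
  expect_length(s$above_average_ids, 12)
  expect_true(all(c("dimension", "dimension_name") %in% names(s$indices)))
  # single attribute: mean equals its ID, nothing strictly above it
  one <- summarize_survey(tibble::tibble(attribute = "X1", f_M = 5L, f_O = 3L,
                                         f_A = 2L, f_I = 0L))
  expect_equal(one$mean_importance, one$indices$importance_degree)
  expect_length(one$above_average_ids, 0)
})

test_that("reference audit matches consistent cells and flags the known ones", {
  audit <- compare_reference(kano_indices(sports_demand_counts()))
  expect_equal(nrow(audit), 23 * 5)
  exact <- subset(audit, quantity %in% c("importance_degree",
                                         "total_satisfaction",
                                         "category_strength"))
  expect_true(all(exact$match))
  flagged <- subset(audit, !match)[c("attribute", "quantity")]
  flagged <- flagged[order(flagged$attribute, flagged$quantity), ]
  want <- known_discrepant_cells()
  want <- want[order(want$attribute, want$quantity), ]
  expect_equal(as.data.frame(flagged), as.data.frame(want),
               ignore_attr = TRUE)
})
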