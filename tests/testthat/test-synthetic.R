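test_that("tabulate after generate_from_counts is the identity on counts", {
  counts <- sports_demand_counts()
  svy <- generate_from_counts(counts, seed = 1)
  tab <- kano_tabulate(svy)
  for (col in paste0("f_", kano_categories())) {
    expect_equal(tab[[col]], counts[[col]], label = col)
  }
  expect_equal(nrow(svy$data), 436)
})

test_that("round-trip identity holds for arbitrary valid count tables", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      counts <- random_counts(6, n_resp = 80, with_rq = TRUE)
      svy <- generate_from_counts(counts, seed = rep)
      tab <- kano_tabulate(svy)
      for (col in paste0("f_", kano_categories())) {
        expect_equal(tab[[col]], counts[[col]])
      }
    }
  })
})

test_that("generation is seed-deterministic and sensitive to the seed", {
  counts <- sports_demand_counts()[1:3, ]
  a <- generate_from_counts(counts, seed = 99)
  b <- generate_from_counts(counts, seed = 99)
  c <- generate_from_counts(counts, seed = 100)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("an all-one-dimensional spec yields only the (1,5) pair", {
  counts <- tibble::tibble(attribute = "X1", f_M = 0L, f_O = 20L,
                           f_A = 0L, f_I = 0L)
  svy <- generate_from_counts(counts, seed = 2)
  expect_true(all(svy$data$X1_func == 1L))
  expect_true(all(svy$data$X1_dysf == 5L))
})

test_that("counts that do not sum to a common total are rejected", {
  bad <- tibble::tibble(attribute = c("X1", "X2"),
                        f_M = c(5L, 5L), f_O = c(5L, 4L),
                        f_A = 0L, f_I = 0L)
  expect_error(generate_from_counts(bad, seed = 1), "same respondent total")
})

test_that("mixture generation recovers degenerate and stochastic targets", {
  # degenerate: all mass on M
  probs <- tibble::tibble(attribute = "X1", p_M = 1, p_O = 0, p_A = 0, p_I = 0)
  svy <- generate_mixture(probs, n = 10, seed = 5)
  tab <- kano_tabulate(svy)
  expect_equal(tab$f_M, 10L)
  expect_equal(classify_attribute(tab$f_M, tab$f_O, tab$f_A, tab$f_I), "M")
  # law of large numbers: empirical frequencies within 3 binomial SD at n = 10000
  probs <- tibble::tibble(attribute = "X1", p_M = 0.5, p_O = 0.2,
                          p_A = 0.2, p_I = 0.1)
  n <- 10000
  tab <- kano_tabulate(generate_mixture(probs, n = n, seed = 6))
  p <- c(0.5, 0.2, 0.2, 0.1)
  got <- c(tab$f_M, tab$f_O, tab$f_A, tab$f_I) / n
  expect_true(all(abs(got - p) <= 3 * sqrt(p * (1 - p) / n)))
  expect_error(
    generate_mixture(tibble::tibble(attribute = "X1", p_M = 0.5, p_O = 0.2,
                                    p_A = 0.2, p_I = 0.2), n = 5, seed = 1),
    "sum to 1"
  )
})

test_that("dominant-category recovery improves with sample size", {
  probs <- tibble::tibble(attribute = "X1", p_M = 0.4, p_O = 0.25,
                          p_A = 0.25, p_I = 0.1)
  recover_rate <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      tab <- kano_tabulate(generate_mixture(probs, n = n, seed = s))
      classify_attribute(tab$f_M, tab$f_O, tab$f_A, tab$f_I) == "M"
    }, logical(1)))
  }
  expect_gte(recover_rate(800, 1:40), recover_rate(20, 1:40))
})

test_that("latent-factor Likert generation is seeded and spans the scale", {
  spec <- tibble::tibble(item = paste0("x", 1:4),
                         dimension = c("A", "A", "B", "B"), loading = 0.7)
  m1 <- generate_likert_factor(spec, n = 500, seed = 77)
  m2 <- generate_likert_factor(spec, n = 500, seed = 77)
  expect_identical(m1, m2)
  expect_true(all(m1 %in% 1:5))
  expect_equal(attr(m1, "dimension"), c(x1 = "A", x2 = "A", x3 = "B", x4 = "B"))
  # zero loading -> independent items -> alpha near 0
  spec0 <- tibble::tibble(item = paste0("x", 1:4), dimension = "A", loading = 0)
  expect_lt(abs(cronbach_alpha(generate_likert_factor(spec0, n = 4000, seed = 9))), 0.1)
  expect_error(generate_likert_factor(spec, n = 10, seed = 1,
                                      cutpoints = c(1, 0, 2, 3)),
               "increasing")
})
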