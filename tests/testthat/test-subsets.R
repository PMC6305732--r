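test_that("subset enumeration is complete and lexicographic", {
  # counts match the multiplicative binomial formula for a range of sizes
  binom <- function(m, k) prod((m - k + 1):m) / prod(1:k)
  for (m in c(3, 5, 8)) {
    for (k in seq_len(m)) {
      subs <- enumerate_subsets(m, k)
      expect_equal(length(subs), binom(m, k))
      expect_equal(length(unique(vapply(subs, paste, character(1),
                                        collapse = "+"))), length(subs))
    }
  }
  subs <- enumerate_subsets(c("a", "b", "c", "d"), 2)
  expect_equal(subs[[1]], c("a", "b"))
  expect_equal(subs[[2]], c("a", "c"))
  expect_equal(subs[[6]], c("c", "d"))
  expect_equal(enumerate_subsets(4, 4) |> length(), 1)
  expect_error(enumerate_subsets(4, 5), "between")
})

test_that("the discriminant search finds a planted informative variable", {
  df <- tiny_cohort(n_asd = 25, n_td = 25, m = 4, sep = 0, seed = 51)
  df$v2 <- df$v2 + ifelse(df$cohort == "ASD", 3, 0) # the planted signal
  res <- search_fda(df, 1, measures = paste0("v", 1:4))
  expect_equal(res$subset[[1]], "v2")
  expect_gt(res$value[1], 0.95)
})

test_that("duplicated columns score identically (symmetry)", {
  df <- tiny_cohort(n_asd = 15, n_td = 15, m = 2, sep = 0, seed = 52)
  df$v1 <- df$v1 + ifelse(df$cohort == "ASD", 2, 0)
  df$v3 <- df$v1 # exact duplicate of the informative measure
  res <- search_fda(df, 2, measures = c("v1", "v2", "v3"))
  v12 <- res$value[res$subset_id == "v1+v2"]
  v23 <- res$value[res$subset_id == "v2+v3"]
  expect_equal(v12, v23, tolerance = 1e-9)
})

test_that("search ranking matches an independent per-subset refit loop", {
  df <- tiny_cohort(n_asd = 12, n_td = 10, m = 4, sep = 0.6, seed = 53)
  res <- search_fda(df, 2, measures = paste0("v", 1:4))
  for (i in seq_len(nrow(res))) {
    model <- fit_fda(df, res$subset[[i]])
    expect_equal(res$value[i], model$c_statistic, tolerance = 1e-10)
  }
  expect_true(all(diff(res$value) <= 1e-12))
})

test_that("degenerate subsets are scored 0.5 and flagged, not dropped", {
  # both cohort means at the origin in both measures
  df <- tibble::tibble(
    v1 = c(1, -1, 2, -2), v2 = c(3, -3, 1, -1),
    cohort = c("ASD", "ASD", "TD", "TD")
  )
  res <- search_fda(df, 2, measures = c("v1", "v2"))
  expect_equal(nrow(res), 1)
  expect_equal(res$value, 0.5)
  expect_true(res$degenerate)
})

test_that("the regression search recovers a planted predictor pair", {
  withr::with_seed(54, {
    n <- 30
    x <- matrix(rnorm(n * 6), n, 6)
    df <- tibble::as_tibble(as.data.frame(x))
    names(df) <- paste0("d", 1:6)
    df$dvabs <- x[, 2] - 1.5 * x[, 5] # noise-free planted pair
  })
  res <- search_kpls(df, 2, predictors = paste0("d", 1:6), components = 3)
  expect_equal(sort(res$subset[[1]]), c("d2", "d5"))
  expect_gt(res$value[1], 0.8)
})

test_that("searching the full panel equals scoring it directly", {
  df <- delta_fixture(n = 15, p = 3, seed = 55)
  res <- search_kpls(df, 3, predictors = paste0("d", 1:3), components = 2,
                     width = 2)
  expect_equal(nrow(res), 1)
  expect_equal(res$value, loo_r2(df, paste0("d", 1:3), components = 2,
                                 width = 2))
})

test_that("frequency analysis counts memberships among qualifying subsets", {
  subs <- enumerate_subsets(c("a", "b", "c", "d"), 2)
  res <- structure(
    tibble::tibble(
      subset = subs,
      subset_id = vapply(subs, paste, character(1), collapse = "+"),
      k = 2, criterion = "c_statistic",
      value = c(0.99, rep(0.6, 5)), # only {a, b} qualifies
      degenerate = FALSE
    ),
    class = c("subset_search", class(tibble::tibble())),
    measures = c("a", "b", "c", "d")
  )
  fr <- frequency_analysis(res, 0.9)
  expect_equal(fr$pct, c(100, 100, 0, 0))
  expect_equal(attr(fr, "n_qualifying"), 1)

  # two disjoint qualifying subsets: each member in half the models
  res$value <- c(0.99, rep(0.6, 4), 0.99) # {a,b} and {c,d}
  fr2 <- frequency_analysis(res, 0.9)
  expect_equal(fr2$pct, rep(50, 4))

  expect_error(frequency_analysis(res, 1.1), "1.1")
})

test_that("an all-pass threshold gives every measure frequency k/m", {
  m <- 6
  k <- 2
  subs <- enumerate_subsets(paste0("x", 1:m), k)
  res <- structure(
    tibble::tibble(
      subset = subs,
      subset_id = vapply(subs, paste, character(1), collapse = "+"),
      k = k, criterion = "c_statistic",
      value = withr::with_seed(56, runif(length(subs), 0.5, 1)),
      degenerate = FALSE
    ),
    class = c("subset_search", class(tibble::tibble())),
    measures = paste0("x", 1:m)
  )
  fr <- frequency_analysis(res, 0)
  expect_equal(fr$pct, rep(100 * k / m, m))
  # membership bookkeeping: percentages sum to 100 k
  expect_equal(sum(fr$pct), 100 * k)
})

test_that("best-per-size curves report the maximum at each size", {
  df <- tiny_cohort(n_asd = 15, n_td = 15, m = 3, sep = 0.8, seed = 57)
  best <- best_by_size(df, 1:3, measures = paste0("v", 1:3))
  expect_equal(best$k, 1:3)
  full <- search_fda(df, 2, measures = paste0("v", 1:3))
  expect_equal(best$best_value[2], full$value[1])
})
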