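test_that("scatter matrices match explicit outer-product arithmetic", {
  # 2 points per cohort in 2-D, computed by hand-rolled loops in the helper
  x <- rbind(c(1, 2), c(3, 0), c(-1, -1), c(0, -3))
  is_asd <- c(TRUE, TRUE, FALSE, FALSE)
  df <- tibble::tibble(v1 = x[, 1], v2 = x[, 2],
                       cohort = ifelse(is_asd, "ASD", "TD"))
  sc <- scatter_matrices(df, c("v1", "v2"))
  oracle <- scatter_oracle(x, is_asd)
  expect_equal(unname(sc$s_b), oracle$s_b, tolerance = 1e-12)
  expect_equal(unname(sc$s_w), oracle$s_w, tolerance = 1e-12)
  expect_true(isSymmetric(sc$s_b))
  expect_true(isSymmetric(sc$s_w))
  expect_true(all(eigen(sc$s_w, only.values = TRUE)$values > -1e-10))
})

test_that("scatter matrices vanish in the degenerate configurations", {
  # coincident cohort means: no between-class scatter
  df <- tibble::tibble(v1 = c(1, -1, 2, -2), v2 = c(0, 0, 1, -1),
                       cohort = c("ASD", "ASD", "TD", "TD"))
  sc <- scatter_matrices(df, c("v1", "v2"))
  expect_equal(unname(sc$s_b), matrix(0, 2, 2), tolerance = 1e-12)

  # single point per cohort: no within-class scatter
  df1 <- tibble::tibble(v1 = c(1, 0), v2 = c(2, 0), cohort = c("ASD", "TD"))
  sc1 <- scatter_matrices(df1, c("v1", "v2"))
  expect_equal(unname(sc1$s_w), matrix(0, 2, 2), tolerance = 1e-12)

  expect_error(scatter_matrices(df[df$cohort == "ASD", ], c("v1", "v2")),
               "non-empty")
})

test_that("fitted direction matches the two-class closed form", {
  for (seed in 1:20) {
    df <- tiny_cohort(n_asd = 12, n_td = 9, m = 5, sep = 0.8, seed = seed)
    model <- fit_fda(df, paste0("v", 1:5))
    # closed form on the same normalized data and the same weighted S_W
    norm <- zscore_apply(df, model$params)
    x <- as.matrix(norm[, paste0("v", 1:5)])
    oracle <- scatter_oracle(x, df$cohort == "ASD")
    ridge <- 1e-8 * sum(diag(oracle$s_w)) / 5
    d <- colMeans(x[df$cohort == "ASD", ]) - colMeans(x[df$cohort == "TD", ])
    w_ref <- solve(oracle$s_w + diag(ridge, 5), d)
    w_ref <- w_ref / sqrt(sum(w_ref^2))
    cosang <- abs(sum(w_ref * model$w))
    expect_gt(cosang, 1 - 1e-8)
    expect_equal(sum(model$w^2), 1, tolerance = 1e-12)
    expect_gt(mean(model$t_asd), mean(model$t_td))
  }
})

test_that("one-dimensional fits orient the positive axis toward ASD", {
  df <- tibble::tibble(v1 = c(5, 6, 1, 2), cohort = c("ASD", "ASD", "TD", "TD"))
  model <- fit_fda(df, "v1")
  expect_equal(unname(abs(model$w)), 1)
  expect_gt(mean(model$t_asd), mean(model$t_td))

  # flipping the class locations flips the projection sign
  df2 <- df
  df2$cohort <- rev(df2$cohort)
  model2 <- fit_fda(df2, "v1")
  expect_equal(unname(model2$w), -unname(model$w))
})

test_that("identical class means are flagged as degenerate", {
  df <- tibble::tibble(v1 = c(1, -1, 2, -2), v2 = c(3, -3, 1, -1),
                       cohort = c("ASD", "ASD", "TD", "TD"))
  expect_warning(model <- fit_fda(df, c("v1", "v2")), "degenerate")
  expect_true(model$degenerate)
  expect_lt(model$j, 1e-8)
})

test_that("scoring is the plain dot product and is linear", {
  df <- tiny_cohort(m = 3, seed = 2)
  model <- fit_fda(df, c("v1", "v2", "v3"))
  x <- c(0.3, -1.1, 2.0)
  expect_equal(score_fda(model, x), sum(x * model$w))
  expect_equal(score_fda(model, 2.5 * x), 2.5 * score_fda(model, x))
  # axis-aligned projection with a hand-built model
  model$w <- c(v1 = 1, v2 = 0, v3 = 0)
  expect_equal(score_fda(model, c(3.2, -7, 100)), 3.2)
  expect_error(score_fda(model, c(1, 2)), "mismatch")
})

test_that("the C-statistic is the Mann-Whitney pair fraction", {
  expect_equal(c_statistic(c(2, 3), c(0, 1)), 1)
  expect_equal(c_statistic(c(0, 1), c(0, 1)), 0.5)
  expect_equal(c_statistic(c(1, 3), 2), 0.5) # 1 win of 2 pairs

  # brute-force pair counting on a random instance with ties
  pos <- c(0.2, 1.5, 1.5, 3, -1)
  neg <- c(0.2, 1.0, 2.5)
  wins <- 0
  for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
  expect_equal(c_statistic(pos, neg), wins / (length(pos) * length(neg)))

  # invariant under strictly increasing transforms
  expect_equal(c_statistic(exp(pos), exp(neg)), c_statistic(pos, neg))
  expect_error(c_statistic(numeric(0), neg), "non-empty")
})

test_that("no random direction beats the fitted Fisher criterion", {
  df <- tiny_cohort(n_asd = 15, n_td = 12, m = 4, sep = 0.7, seed = 9)
  model <- fit_fda(df, paste0("v", 1:4))
  norm <- zscore_apply(df, model$params)
  x <- as.matrix(norm[, paste0("v", 1:4)])
  oracle <- scatter_oracle(x, df$cohort == "ASD")
  j_of <- function(w) {
    drop(crossprod(w, oracle$s_b %*% w)) / drop(crossprod(w, oracle$s_w %*% w))
  }
  j_fit <- j_of(model$w)
  withr::with_seed(11, {
    for (i in 1:1000) {
      v <- rnorm(4)
      v <- v / sqrt(sum(v^2))
      expect_lte(j_of(v), j_fit * (1 + 1e-8))
    }
  })
})

test_that("sample order does not change the fit", {
  df <- tiny_cohort(n_asd = 8, n_td = 8, m = 3, seed = 5)
  perm <- withr::with_seed(2, sample(nrow(df)))
  m1 <- fit_fda(df, paste0("v", 1:3))
  m2 <- fit_fda(df[perm, ], paste0("v", 1:3))
  expect_equal(m1$w, m2$w, tolerance = 1e-10)
  expect_equal(sort(m1$t_asd), sort(m2$t_asd), tolerance = 1e-10)
  expect_equal(m1$c_statistic, m2$c_statistic)
})

test_that("confusion metrics report undefined rates as NA", {
  all_right <- confusion_metrics(c("ASD", "TD"), c("ASD", "TD"))
  expect_equal(unlist(all_right[, c("tpr", "tnr", "ppv", "npv")]),
               c(tpr = 1, tnr = 1, ppv = 1, npv = 1))

  all_pos <- confusion_metrics(rep("ASD", 4), c("ASD", "ASD", "TD", "TD"))
  expect_equal(all_pos$tnr, 0)
  expect_true(is.na(all_pos$npv))

  cm <- confusion_metrics(
    c(rep("ASD", 9), "TD", rep("TD", 8), rep("ASD", 2)),
    c(rep("ASD", 10), rep("TD", 10))
  )
  expect_equal(cm$tp, 9)
  expect_equal(cm$tpr, 0.9)
  expect_equal(cm$tnr, 0.8)
  expect_equal(cm$ppv, 9 / 11)
  expect_equal(cm$npv, 8 / 9)
})

test_that("a frozen model survives a JSON round trip", {
  df <- tiny_cohort(m = 3, seed = 7)
  model <- fit_fda(df, paste0("v", 1:3))
  path <- withr::local_tempfile(fileext = ".json")
  write_fda_json(model, path)
  back <- read_fda_json(path)
  expect_equal(back$w, model$w)
  expect_equal(back$params$mean, model$params$mean)
  new_point <- tibble::tibble(v1 = 0.2, v2 = -0.4, v3 = 1)
  expect_equal(predict(back, new_point), predict(model, new_point))
})

test_that("tidy and glance expose the model in rectangular form", {
  df <- tiny_cohort(m = 3, seed = 8)
  model <- fit_fda(df, paste0("v", 1:3))
  td <- tidy(model)
  expect_equal(td$measure, paste0("v", 1:3))
  expect_equal(td$weight, unname(model$w))
  gl <- glance(model)
  expect_equal(gl$n_asd, 10)
  expect_equal(gl$c_statistic, model$c_statistic)
})
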