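test_that("the Gaussian kernel follows its closed form", {
  expect_equal(gaussian_kernel_matrix(c(0, 0), c(3, 4), width = 5)[1, 1],
               exp(-0.5))
  x <- matrix(rnorm(6), 3, 2)
  k <- gaussian_kernel_matrix(x, x, width = 1.3)
  expect_equal(diag(k), rep(1, 3))
  expect_true(isSymmetric(k))
  expect_true(all(eigen(k, only.values = TRUE)$values > -1e-10))
  expect_lt(gaussian_kernel_matrix(0, 1e4, width = 1)[1, 1], 1e-300)
  expect_error(gaussian_kernel_matrix(1, 2, width = 0), "width")
  expect_error(gaussian_kernel_matrix(matrix(1, 1, 2), matrix(1, 1, 3), 1),
               "dimensionality")
})

test_that("a constant response is predicted exactly everywhere", {
  df <- delta_fixture(n = 10)
  df$dvabs <- 7.5
  fit <- suppressWarnings(fit_kpls(df, paste0("d", 1:3), components = 2))
  expect_equal(fit$fitted, rep(7.5, 10))
  far <- tibble::tibble(d1 = 100, d2 = -100, d3 = 100)
  expect_equal(predict(fit, far), 7.5)
})

test_that("linear-kernel full-component fits reproduce least squares", {
  df <- delta_fixture(n = 14, p = 3, seed = 43)
  fit <- fit_kpls(df, paste0("d", 1:3), components = 3, kernel = "linear")
  ols <- lm(dvabs ~ d1 + d2 + d3, data = df)
  expect_equal(fit$fitted, unname(fitted(ols)), tolerance = 1e-6)
  newx <- tibble::tibble(d1 = c(0.3, -1), d2 = c(1, 0.5), d3 = c(-0.2, 2))
  expect_equal(predict(fit, newx), unname(predict(ols, newx)),
               tolerance = 1e-6)
})

test_that("the dual-form fit matches an independently coded oracle", {
  df <- delta_fixture(n = 6, p = 2, seed = 44)
  x <- as.matrix(df[, c("d1", "d2")])
  width <- 1.5
  for (ncomp in 1:3) {
    fit <- fit_kpls(df, c("d1", "d2"), components = ncomp, width = width,
                    normalize = FALSE)
    test_x <- matrix(c(0.2, -0.4, 1.1, 0.8), 2, 2)
    test_df <- tibble::tibble(d1 = test_x[, 1], d2 = test_x[, 2])
    expect_equal(predict(fit, test_df, normalize = FALSE),
                 kpls_oracle(x, df$dvabs, test_x, width, ncomp),
                 tolerance = 1e-8)
  }
})

test_that("training predictions reproduce the stored fitted values", {
  df <- delta_fixture(n = 15)
  fit <- fit_kpls(df, paste0("d", 1:3), components = 4)
  expect_equal(predict(fit, df), fit$fitted, tolerance = 1e-8)
})

test_that("points far from all training data saturate near the response mean", {
  # the Gaussian kernel vanishes, so the prediction collapses to the
  # constant ybar - <mean feature, regression direction>: identical for any
  # remote point and close to the training response mean
  df <- delta_fixture(n = 12)
  fit <- fit_kpls(df, paste0("d", 1:3), components = 3)
  far1 <- tibble::tibble(d1 = 1e4, d2 = -1e4, d3 = 1e4)
  far2 <- tibble::tibble(d1 = -2e4, d2 = 3e4, d3 = 1e4)
  expect_equal(predict(fit, far1), predict(fit, far2), tolerance = 1e-10)
  expect_lt(abs(predict(fit, far1) - mean(df$dvabs)), 0.5 * sd(df$dvabs))
})

test_that("duplicating every training row leaves the fit unchanged", {
  df <- delta_fixture(n = 8)
  doubled <- dplyr::bind_rows(df, df)
  newx <- tibble::tibble(d1 = c(0, 1), d2 = c(0.5, -1), d3 = c(0.1, 0.7))
  f1 <- fit_kpls(df, paste0("d", 1:3), components = 2, width = 2,
                 normalize = FALSE)
  f2 <- fit_kpls(doubled, paste0("d", 1:3), components = 2, width = 2,
                 normalize = FALSE)
  expect_equal(predict(f1, newx, normalize = FALSE),
               predict(f2, newx, normalize = FALSE), tolerance = 1e-8)
})

test_that("fitted R^2 is monotone in the number of components", {
  df <- delta_fixture(n = 18)
  r2 <- vapply(1:6, function(a) {
    fit_kpls(df, paste0("d", 1:3), components = a, width = 1.5)$r2
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
})

test_that("predictions are equivariant to response translation", {
  df <- delta_fixture(n = 12)
  shifted <- df
  shifted$dvabs <- df$dvabs + 100
  newx <- tibble::tibble(d1 = 0.2, d2 = -0.3, d3 = 0.9)
  f1 <- fit_kpls(df, paste0("d", 1:3), components = 2, width = 1.5)
  f2 <- fit_kpls(shifted, paste0("d", 1:3), components = 2, width = 1.5)
  expect_equal(predict(f2, newx), predict(f1, newx) + 100, tolerance = 1e-8)
})

test_that("leave-one-out recovers an exact linear signal perfectly", {
  df <- tibble::tibble(d1 = seq(-2, 2, length.out = 12))
  df$dvabs <- 2 * df$d1
  r2 <- loo_r2(df, "d1", components = 1, kernel = "linear")
  expect_equal(r2, 1, tolerance = 1e-9)
})

test_that("leave-one-out matches a manually unrolled fold loop", {
  df <- delta_fixture(n = 4, p = 2, seed = 45)
  width <- 2
  cv <- loo_kpls(df, c("d1", "d2"), components = 2, width = width,
                 normalize = FALSE)
  pred <- numeric(4)
  for (i in 1:4) {
    pred[i] <- kpls_oracle(as.matrix(df[-i, c("d1", "d2")]),
                           df$dvabs[-i],
                           as.matrix(df[i, c("d1", "d2")]),
                           width, 2)
  }
  r2_manual <- 1 - sum((df$dvabs - pred)^2) / sum((df$dvabs - mean(df$dvabs))^2)
  expect_equal(cv$r2, r2_manual, tolerance = 1e-8)
  expect_equal(cv$predictions$y_pred, pred, tolerance = 1e-8)
})

test_that("cross-validation rejects a zero-variance response", {
  df <- delta_fixture(n = 8)
  df$dvabs <- 3
  expect_error(loo_kpls(df, paste0("d", 1:3), components = 1),
               "zero variance")
})

test_that("component requests beyond the possible rank are truncated", {
  df <- delta_fixture(n = 6)
  expect_warning(fit <- fit_kpls(df, paste0("d", 1:3), components = 10),
                 "reduced|rank")
  expect_lte(fit$components, 5)
})
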