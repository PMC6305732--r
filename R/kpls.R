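#' Gaussian kernel matrix between two sets of vectors
#'
#' \eqn{K_{ij} = \exp(-\|a_i - b_j\|^2 / (2\,\mathrm{width}^2))}. Symmetric
#' positive semidefinite when the two sets coincide.
#'
#' @param a,b Numeric matrices with one row per sample and matching numbers
#'   of columns (vectors are treated as single rows).
#' @param width Kernel width (> 0), in the units of the input vectors.
#' @return A `nrow(a)` x `nrow(b)` kernel matrix.
#' @export
#' @examples
#' gaussian_kernel_matrix(c(0, 0), c(3, 4), width = 5) # exp(-0.5)
gaussian_kernel_matrix <- function(a, b, width) {
  if (!is.matrix(a)) a <- matrix(a, nrow = 1)
  if (!is.matrix(b)) b <- matrix(b, nrow = 1)
  if (ncol(a) != ncol(b)) abort("dimensionality mismatch between a and b")
  if (!is.finite(width) || width <= 0) abort("kernel width must be > 0")
  sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sq[sq < 0] <- 0
  exp(-sq / (2 * width^2))
}

linear_kernel_matrix <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(a, nrow = 1)
  if (!is.matrix(b)) b <- matrix(b, nrow = 1)
  if (ncol(a) != ncol(b)) abort("dimensionality mismatch between a and b")
  tcrossprod(a, b)
}

kernel_matrix <- function(a, b, width, kernel) {
  switch(kernel,
    gaussian = gaussian_kernel_matrix(a, b, width),
    linear = linear_kernel_matrix(a, b),
    abort(paste0("unknown kernel '", kernel, "'"))
  )
}

#' Median-distance heuristic for the Gaussian kernel width
#'
#' The median pairwise Euclidean distance among the (normalized) training
#' vectors: scale-adaptive, deterministic, and recorded with every fit.
#'
#' @param x Numeric matrix of training vectors (rows = samples).
#' @return The median pairwise distance.
#' @export
median_heuristic_width <- function(x) {
  d <- as.numeric(dist(x))
  w <- median(d)
  if (!is.finite(w) || w <= 0) {
    abort("median pairwise distance is zero; pass `width` explicitly")
  }
  w
}

# dual-form kernel PLS (NIPALS with score-based deflation of the centered
# kernel and the response); univariate response
kpls_core <- function(kc, yc, ncomp) {
  n <- nrow(kc)
  t_mat <- matrix(0, n, ncomp)
  u_mat <- matrix(0, n, ncomp)
  kd <- kc
  yd <- yc
  used <- 0
  for (a in seq_len(ncomp)) {
    u <- yd
    if (sqrt(sum(u^2)) < 1e-12) break
    t_vec <- drop(kd %*% u)
    t_norm <- sqrt(sum(t_vec^2))
    if (t_norm < 1e-12) break
    t_vec <- t_vec / t_norm
    t_mat[, a] <- t_vec
    u_mat[, a] <- u
    # deflate: Kd <- (I - t t') Kd (I - t t'); Yd <- Yd - t t' Yd
    kd <- kd - tcrossprod(t_vec, drop(crossprod(kd, t_vec)))
    kd <- kd - tcrossprod(drop(kd %*% t_vec), t_vec)
    yd <- yd - t_vec * drop(crossprod(t_vec, yd))
    used <- a
  }
  if (used == 0) {
    return(list(b = matrix(0, n, 1), components = 0L))
  }
  t_mat <- t_mat[, seq_len(used), drop = FALSE]
  u_mat <- u_mat[, seq_len(used), drop = FALSE]
  b <- u_mat %*% solve(crossprod(t_mat, kc %*% u_mat),
                       drop(crossprod(t_mat, yc)))
  list(b = b, components = used)
}

#' Fit a Gaussian-kernel partial least squares regression
#'
#' Regresses a scalar response (change in VABS Composite) on a set of
#' metabolite-change predictors through a kernel-induced feature space:
#' the predictors are z-scored, the response centered, the training kernel
#' matrix double-centered, and latent components extracted one at a time as
#' directions of maximal covariance between the centered kernel and the
#' residual response, deflating both between components. The regression is
#' carried entirely in the dual (sample) space, so the model is defined by
#' one coefficient per training sample.
#'
#' @param data Data frame of per-participant changes (e.g. from
#'   [delta_table()]).
#' @param predictors Character vector of predictor column names.
#' @param response Response column name (default `"dvabs"`).
#' @param components Number of latent components; `NULL` selects it by a
#'   leave-one-out sweep over `1..min(10, n - 2)` on the training data.
#'   Requests beyond the extractable rank are truncated with a warning.
#' @param width Gaussian kernel width; `NULL` uses
#'   [median_heuristic_width()] of the z-scored predictors.
#' @param kernel `"gaussian"` (the supported kernel) or `"linear"`, which is
#'   retained for validation because linear-kernel PLS with full components
#'   reproduces ordinary least squares on full-rank data.
#' @param normalize If `FALSE`, predictors are used as-is and identity
#'   normalization parameters are stored.
#' @return An object of class `kpls_model`.
#' @export
fit_kpls <- function(data, predictors, response = "dvabs",
                     components = NULL, width = NULL,
                     kernel = c("gaussian", "linear"), normalize = TRUE) {
  kernel <- match.arg(kernel)
  data <- as_tibble(data)
  missing_cols <- setdiff(c(predictors, response), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(data)
  if (n < 2) abort("need at least 2 samples")
  y <- data[[response]]
  if (any(!is.finite(y))) abort("non-finite response values")
  if (normalize) {
    params <- zscore_fit(data, predictors)
    x <- as.matrix(zscore_apply(data, params, predictors)[, predictors])
  } else {
    params <- structure(
      tibble(measure = predictors, mean = 0, sd = 1),
      class = c("zscore_params", "tbl_df", "tbl", "data.frame")
    )
    x <- as.matrix(data[, predictors])
  }
  if (kernel == "gaussian" && is.null(width)) {
    width <- median_heuristic_width(x)
  }
  if (is.null(components)) {
    components <- select_kpls_components(data, predictors, response,
                                         width = width, kernel = kernel,
                                         normalize = normalize)
  }
  if (components > n - 1) {
    warn(paste0("components reduced from ", components, " to n - 1 = ", n - 1))
    components <- n - 1
  }
  y_mean <- mean(y)
  yc <- y - y_mean
  k <- kernel_matrix(x, x, width, kernel)
  h <- diag(n) - matrix(1 / n, n, n)
  kc <- h %*% k %*% h
  kc <- (kc + t(kc)) / 2
  core <- kpls_core(kc, yc, components)
  if (core$components < components) {
    warn(paste0("rank limited: extracted ", core$components, " of ",
                components, " requested components"))
  }
  fitted <- drop(kc %*% core$b) + y_mean
  structure(
    list(
      predictors = predictors, response = response,
      x_train = x, params = params,
      y = y, y_mean = y_mean,
      width = width, kernel = kernel,
      components = core$components,
      dual_coef = core$b,
      k_col_means = colMeans(k),
      fitted = fitted,
      r2 = 1 - sum((y - fitted)^2) / sum((y - y_mean)^2)
    ),
    class = "kpls_model"
  )
}

#' Predict from a fitted kernel PLS model
#'
#' Evaluates the kernel between new (normalized) vectors and the training
#' vectors, centers it with the training centering statistics, projects it
#' through the dual coefficients, and de-centers to the response scale. For
#' a test point far from all training points the Gaussian kernel vanishes
#' and the prediction saturates to a constant near the training response
#' mean.
#'
#' @param object A `kpls_model`.
#' @param newdata Data frame carrying the model's predictor columns (raw
#'   scale unless `normalize = FALSE`).
#' @param normalize Set to `FALSE` if `newdata` is already normalized with
#'   the model's training parameters.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.kpls_model <- function(object, newdata, normalize = TRUE, ...) {
  newdata <- as_tibble(newdata)
  missing_cols <- setdiff(object$predictors, names(newdata))
  if (length(missing_cols) > 0) {
    abort(paste0("newdata is missing predictor(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (normalize) {
    newdata <- zscore_apply(newdata, object$params, object$predictors)
  }
  x_new <- as.matrix(newdata[, object$predictors, drop = FALSE])
  if (ncol(x_new) != ncol(object$x_train)) {
    abort("dimensionality mismatch with the training predictors")
  }
  k_t <- kernel_matrix(x_new, object$x_train, object$width, object$kernel)
  a <- sweep(k_t, 2, object$k_col_means)
  k_tc <- a - rowMeans(a)
  drop(k_tc %*% object$dual_coef) + object$y_mean
}

# inner LOO sweep over component counts on the supplied training data;
# smallest count wins ties
select_kpls_components <- function(data, predictors, response, width,
                                   kernel, normalize = TRUE,
                                   max_components = 10) {
  n <- nrow(data)
  a_max <- min(max_components, n - 2)
  if (a_max < 1) return(1L)
  y <- data[[response]]
  r2 <- vapply(seq_len(a_max), function(a) {
    pred <- vapply(seq_len(n), function(i) {
      fit <- fit_kpls(data[-i, , drop = FALSE], predictors, response,
                      components = a, width = width, kernel = kernel,
                      normalize = normalize)
      predict(fit, data[i, , drop = FALSE], normalize = normalize)
    }, numeric(1))
    1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }, numeric(1))
  which.max(r2)
}

#' Leave-one-out cross-validated kernel PLS
#'
#' Each sample is held out in turn; the predictor normalization, kernel
#' width (when data-driven) and the regression model are refit on the other
#' n - 1 samples, and the held-out response is predicted. The
#' cross-validated coefficient of determination is
#' \eqn{R^2 = 1 - \sum_i (y_i - \hat y_{-i})^2 / \sum_i (y_i - \bar y)^2},
#' which may be negative when the model predicts worse than the mean.
#'
#' When `components` is `NULL` it is selected once, by an inner
#' leave-one-out sweep over `1..min(10, n - 2)` on the training set of the
#' first fold, and held fixed for all folds.
#'
#' @inheritParams fit_kpls
#' @return An object of class `kpls_cv`: list with `r2`, a `predictions`
#'   tibble (`y`, `y_pred`), `components`, `kernel`, and the `width`
#'   specification used (`"median heuristic (per fold)"` or a number).
#' @export
loo_kpls <- function(data, predictors, response = "dvabs",
                     components = NULL, width = NULL,
                     kernel = c("gaussian", "linear"), normalize = TRUE) {
  kernel <- match.arg(kernel)
  data <- as_tibble(data)
  n <- nrow(data)
  if (n < 3) abort("need at least 3 samples for leave-one-out validation")
  y <- data[[response]]
  if (var(y) == 0) abort("response has zero variance; R^2 is undefined")
  if (is.null(components)) {
    components <- select_kpls_components(
      data[-1, , drop = FALSE], predictors, response,
      width = width, kernel = kernel, normalize = normalize
    )
  }
  pred <- vapply(seq_len(n), function(i) {
    fit <- fit_kpls(data[-i, , drop = FALSE], predictors, response,
                    components = components, width = width, kernel = kernel,
                    normalize = normalize)
    predict(fit, data[i, , drop = FALSE], normalize = normalize)
  }, numeric(1))
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  structure(
    list(
      r2 = r2,
      predictions = tibble(y = y, y_pred = pred),
      components = components, kernel = kernel,
      width = width %||% "median heuristic (per fold)",
      predictors = predictors, response = response
    ),
    class = "kpls_cv"
  )
}

#' Cross-validated R-squared
#'
#' Convenience wrapper around [loo_kpls()] returning just the
#' cross-validated \eqn{R^2}.
#'
#' @inheritParams loo_kpls
#' @return A single number (possibly negative).
#' @export
loo_r2 <- function(data, predictors, response = "dvabs",
                   components = NULL, width = NULL,
                   kernel = c("gaussian", "linear"), normalize = TRUE) {
  loo_kpls(data, predictors, response, components = components,
           width = width, kernel = kernel, normalize = normalize)$r2
}

#' @export
print.kpls_model <- function(x, ...) {
  cat("Kernel PLS regression model\n")
  cat("  predictors: ", paste(x$predictors, collapse = ", "), "\n", sep = "")
  cat(sprintf("  n = %d, kernel = %s, width = %.4g, components = %d\n",
              length(x$y), x$kernel, x$width %||% NA_real_, x$components))
  cat(sprintf("  fitted R^2 = %.3f\n", x$r2))
  invisible(x)
}

#' @export
tidy.kpls_model <- function(x, ...) {
  tibble(sample = seq_along(x$y), dual_coef = drop(x$dual_coef),
         y = x$y, fitted = x$fitted)
}

#' @export
glance.kpls_model <- function(x, ...) {
  tibble(
    n = length(x$y), n_predictors = length(x$predictors),
    kernel = x$kernel, width = x$width %||% NA_real_,
    components = x$components, r_squared = x$r2
  )
}

#' @export
print.kpls_cv <- function(x, ...) {
  cat("Leave-one-out cross-validated kernel PLS\n")
  cat("  predictors: ", paste(x$predictors, collapse = ", "), "\n", sep = "")
  cat(sprintf("  components = %d, kernel = %s\n", x$components, x$kernel))
  cat(sprintf("  cross-validated R^2 = %.3f\n", x$r2))
  invisible(x)
}

#' @export
tidy.kpls_cv <- function(x, ...) x$predictions

#' @export
glance.kpls_cv <- function(x, ...) {
  tibble(n = nrow(x$predictions), components = x$components,
         kernel = x$kernel, cv_r_squared = x$r2)
}
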