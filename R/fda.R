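#' Between- and within-class scatter matrices
#'
#' For a two-cohort table of normalized measurements, computes the
#' between-class scatter matrix
#' \deqn{S_B = n_{ASD}(\bar{x}_{ASD}-\bar{x})^T(\bar{x}_{ASD}-\bar{x}) +
#'       n_{TD}(\bar{x}_{TD}-\bar{x})^T(\bar{x}_{TD}-\bar{x})}
#' and the within-class scatter matrix with class-size prefactors
#' \deqn{S_W = n_{ASD}\sum_{i \in ASD}(x_i-\bar{x}_{ASD})^T(x_i-\bar{x}_{ASD})
#'     + n_{TD}\sum_{i \in TD}(x_i-\bar{x}_{TD})^T(x_i-\bar{x}_{TD}).}
#' Note the \eqn{n_{ASD}}/\eqn{n_{TD}} multipliers on each class's summed
#' outer products: this weighted form (rather than the unweighted pooled
#' scatter) is used consistently throughout the package, including in the
#' closed-form two-class solution.
#'
#' @param data Data frame with a `cohort` column (values `ASD` / `TD`) and
#'   the measurement columns, already normalized.
#' @param measures Measurement columns to use (default: canonical measures
#'   present in `data`).
#' @return A list with elements `s_b`, `s_w` (both m x m, symmetric PSD),
#'   the mean vectors `mean_all`, `mean_asd`, `mean_td`, and counts `n_asd`,
#'   `n_td`.
#' @export
scatter_matrices <- function(data, measures = NULL) {
  data <- as_tibble(data)
  if (!"cohort" %in% names(data)) abort("data must carry a 'cohort' column")
  if (is.null(measures)) measures <- intersect(focm_measures(), names(data))
  missing_cols <- setdiff(measures, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing measurement column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- as.matrix(data[, measures, drop = FALSE])
  is_asd <- data$cohort == "ASD"
  n_asd <- sum(is_asd)
  n_td <- sum(!is_asd)
  if (n_asd == 0 || n_td == 0) {
    abort("both cohorts (ASD and TD) must be non-empty")
  }
  x_asd <- x[is_asd, , drop = FALSE]
  x_td <- x[!is_asd, , drop = FALSE]
  mean_all <- colMeans(x)
  mean_asd <- colMeans(x_asd)
  mean_td <- colMeans(x_td)

  d_asd <- mean_asd - mean_all
  d_td <- mean_td - mean_all
  s_b <- n_asd * tcrossprod(d_asd) + n_td * tcrossprod(d_td)

  c_asd <- sweep(x_asd, 2, mean_asd)
  c_td <- sweep(x_td, 2, mean_td)
  s_w <- n_asd * crossprod(c_asd) + n_td * crossprod(c_td)

  dimnames(s_b) <- dimnames(s_w) <- list(measures, measures)
  list(s_b = s_b, s_w = s_w, mean_all = mean_all, mean_asd = mean_asd,
       mean_td = mean_td, n_asd = n_asd, n_td = n_td)
}

# ridge used before inverting a near-singular within-class scatter
sw_ridge <- function(s_w) {
  m <- nrow(s_w)
  1e-8 * sum(diag(s_w)) / m
}

#' Fit a two-class Fisher discriminant model
#'
#' Finds the projection vector `w` maximizing the Fisher criterion
#' \eqn{J(w) = (w^T S_B w) / (w^T S_W w)}, i.e. the leading eigenvector of
#' \eqn{S_W^{-1} S_B}, computed via the numerically stabler symmetric
#' generalized eigenproblem (Cholesky whitening of the regularized
#' \eqn{S_W}). The input table is z-score normalized internally on all of
#' its rows — these are the training normalization parameters stored in the
#' model and applied, frozen, to any later data scored with it.
#'
#' `w` is returned with unit Euclidean norm and oriented so the mean ASD
#' discriminant score exceeds the mean TD score (ASD on the positive axis).
#'
#' @param data Cohort data frame with `cohort` and measurement columns
#'   (raw scale; normalization is fitted here).
#' @param subset Character vector of measure names to use.
#' @param normalize If `FALSE`, `data` is taken as already normalized and
#'   identity parameters are stored.
#' @return An object of class `fda_model` with elements `subset`, `w`,
#'   `params` (class `zscore_params`), `t_asd`, `t_td`, `j` (the attained
#'   Fisher criterion), `c_statistic` (of the fitted scores) and
#'   `degenerate` (TRUE when the class means coincide, leaving no
#'   between-class scatter to project on).
#' @export
fit_fda <- function(data, subset = NULL, normalize = TRUE) {
  data <- as_tibble(data)
  if (is.null(subset)) subset <- intersect(focm_measures(), names(data))
  missing_cols <- setdiff(subset, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("subset names not in table: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (normalize) {
    params <- zscore_fit(data, subset)
    norm <- zscore_apply(data, params, subset)
  } else {
    params <- structure(
      tibble(measure = subset, mean = 0, sd = 1),
      class = c("zscore_params", "tbl_df", "tbl", "data.frame")
    )
    norm <- data
  }
  x <- as.matrix(norm[, subset, drop = FALSE])
  is_asd <- norm$cohort == "ASD"
  core <- fda_direction(x, is_asd)
  if (core$degenerate) {
    warn("degenerate fit: cohort means coincide; discriminant is arbitrary")
  }
  w <- setNames(core$w, subset)
  structure(
    list(subset = subset, w = w, params = params,
         t_asd = core$t_asd, t_td = core$t_td,
         j = core$j,
         c_statistic = c_statistic(core$t_asd, core$t_td),
         degenerate = core$degenerate),
    class = "fda_model"
  )
}

# matrix-level FDA fit on normalized data: eigenvector of S_W^-1 S_B via the
# symmetric whitened problem; used by fit_fda and the exhaustive search
fda_direction <- function(x, is_asd) {
  n_asd <- sum(is_asd)
  n_td <- sum(!is_asd)
  if (n_asd == 0 || n_td == 0) abort("both cohorts must be non-empty")
  m <- ncol(x)
  x_asd <- x[is_asd, , drop = FALSE]
  x_td <- x[!is_asd, , drop = FALSE]
  mean_all <- colMeans(x)
  mean_asd <- colMeans(x_asd)
  mean_td <- colMeans(x_td)
  d_asd <- mean_asd - mean_all
  d_td <- mean_td - mean_all
  s_b <- n_asd * tcrossprod(d_asd) + n_td * tcrossprod(d_td)
  c_asd <- sweep(x_asd, 2, mean_asd)
  c_td <- sweep(x_td, 2, mean_td)
  s_w <- n_asd * crossprod(c_asd) + n_td * crossprod(c_td)
  s_w_reg <- s_w + diag(sw_ridge(s_w), m)
  l <- tryCatch(t(chol(s_w_reg)), error = function(e) {
    abort("within-class scatter is singular beyond regularization")
  })
  li_sb <- forwardsolve(l, s_b)
  a <- t(forwardsolve(l, t(li_sb)))
  a <- (a + t(a)) / 2
  es <- eigen(a, symmetric = TRUE)
  w <- backsolve(t(l), es$vectors[, 1])
  w <- w / sqrt(sum(w^2))
  t_all <- drop(x %*% w)
  if (mean(t_all[is_asd]) < mean(t_all[!is_asd])) {
    w <- -w
    t_all <- -t_all
  }
  j <- drop(crossprod(w, s_b %*% w)) / drop(crossprod(w, s_w_reg %*% w))
  degenerate <- sqrt(sum((mean_asd - mean_td)^2)) < 1e-10 ||
    es$values[1] <= 1e-12
  list(w = w, t_asd = t_all[is_asd], t_td = t_all[!is_asd],
       j = j, degenerate = degenerate)
}

#' Discriminant scores for new data
#'
#' Projects measurement vectors onto the model's discriminant direction:
#' \eqn{t_i = x_i \cdot w}. Raw-scale input is first normalized with the
#' model's frozen training parameters.
#'
#' @param object An `fda_model`.
#' @param newdata Data frame carrying the model's measure subset.
#' @param normalize Set to `FALSE` if `newdata` is already normalized with
#'   the model's parameters.
#' @param ... Unused.
#' @return A numeric vector of discriminant scores, one per row.
#' @export
predict.fda_model <- function(object, newdata, normalize = TRUE, ...) {
  newdata <- as_tibble(newdata)
  missing_cols <- setdiff(object$subset, names(newdata))
  if (length(missing_cols) > 0) {
    abort(paste0("newdata is missing measure(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (normalize) newdata <- zscore_apply(newdata, object$params, object$subset)
  x <- as.matrix(newdata[, object$subset, drop = FALSE])
  drop(x %*% object$w)
}

#' Project an already-normalized measurement vector onto a discriminant
#'
#' Low-level scoring: the dot product \eqn{t = \sum_j x_j w_j} with the
#' model's unit-norm projection vector. Input must already be normalized
#' with the model's training parameters and ordered as `object$subset`.
#'
#' @param object An `fda_model`.
#' @param x Numeric vector (or matrix with one row per sample) over the
#'   model's subset.
#' @return Discriminant score(s).
#' @export
score_fda <- function(object, x) {
  stopifnot(inherits(object, "fda_model"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(object$w)) {
    abort(paste0("length mismatch: expected ", length(object$w),
                 " measures, got ", ncol(x)))
  }
  drop(x %*% object$w)
}

#' Concordance statistic (area under the ROC curve)
#'
#' Rank-based AUC of two score sets: the fraction of (positive, negative)
#' pairs in which the positive score exceeds the negative one, ties counted
#' one half (the Mann-Whitney convention). Ranges from 0.5 (random
#' assignment, by symmetry) to 1.0 (perfect separation); values below 0.5
#' indicate reversed orientation.
#'
#' @param scores_pos Scores of the positive class (ASD).
#' @param scores_neg Scores of the negative class (TD).
#' @return The C-statistic as a single number.
#' @export
#' @examples
#' c_statistic(c(2, 3), c(0, 1)) # 1
#' c_statistic(c(1, 3), 2)       # 0.5
c_statistic <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0 || length(scores_neg) == 0) {
    abort("both score sets must be non-empty")
  }
  n_pos <- length(scores_pos)
  n_neg <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg)) # midranks handle ties as 1/2
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-matrix rates for a two-class prediction
#'
#' Treats ASD as the positive class. Rates with a zero denominator are
#' reported as `NA` (undefined), never as 0.
#'
#' @param predicted,truth Equal-length label vectors with values in
#'   `c("ASD", "TD")`.
#' @param positive The positive-class label.
#' @return A one-row tibble with counts `tp`, `tn`, `fp`, `fn` and rates
#'   `tpr` (sensitivity, TP/(TP+FN)), `tnr` (specificity, TN/(TN+FP)),
#'   `ppv` (TP/(TP+FP)) and `npv` (TN/(TN+FN)).
#' @export
confusion_metrics <- function(predicted, truth, positive = "ASD") {
  if (length(predicted) != length(truth)) {
    abort("predicted and truth must have equal length")
  }
  pos_pred <- predicted == positive
  pos_true <- truth == positive
  tp <- sum(pos_pred & pos_true)
  tn <- sum(!pos_pred & !pos_true)
  fp <- sum(pos_pred & !pos_true)
  fn <- sum(!pos_pred & pos_true)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    tpr = rate(tp, tp + fn), tnr = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp), npv = rate(tn, tn + fn)
  )
}

#' Leave-one-out cross-validated classification
#'
#' For each participant in turn: the discriminant model (including its
#' z-score normalization), the score-density estimates and the balanced
#' error threshold are refit on the remaining participants, and the held-out
#' participant is classified by comparing their score with the refit
#' threshold (score above the threshold rejects "participant is TD").
#'
#' @param data Cohort data frame (raw scale) with `cohort`.
#' @param subset Measure subset for the model.
#' @return A tibble with one row per participant: `cohort`, the
#'   cross-validated `score`, and the `predicted` label.
#' @export
cv_fda <- function(data, subset) {
  data <- as_tibble(data)
  n <- nrow(data)
  if (n < 3) abort("need at least 3 samples for leave-one-out classification")
  res <- purrr::map(seq_len(n), function(i) {
    train <- data[-i, , drop = FALSE]
    model <- fit_fda(train, subset)
    pair <- fit_kde_pair(model$t_td, model$t_asd)
    thr <- find_threshold(pair$td, pair$asd)
    s <- predict(model, data[i, , drop = FALSE])
    tibble(score = s,
           predicted = if (s > thr$h0) "ASD" else "TD")
  })
  out <- bind_rows(res)
  out$cohort <- data$cohort
  out[, c("cohort", "score", "predicted")]
}

#' @export
print.fda_model <- function(x, ...) {
  cat("Fisher discriminant model\n")
  cat("  measures: ", paste(x$subset, collapse = ", "), "\n", sep = "")
  cat(sprintf("  n_ASD = %d, n_TD = %d\n", length(x$t_asd), length(x$t_td)))
  cat(sprintf("  fitted C-statistic = %.4f, J(w) = %.4g%s\n",
              x$c_statistic, x$j,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' @export
tidy.fda_model <- function(x, ...) {
  tibble(measure = x$subset, weight = unname(x$w))
}

#' @export
glance.fda_model <- function(x, ...) {
  tibble(
    n_asd = length(x$t_asd), n_td = length(x$t_td),
    n_measures = length(x$subset),
    j = x$j, c_statistic = x$c_statistic,
    degenerate = x$degenerate
  )
}

#' Serialize a discriminant model to JSON
#'
#' Writes the feature subset, projection vector, normalization parameters,
#' orientation convention and training score sets, so a frozen model can be
#' re-loaded and applied to trial data in a later session.
#'
#' @param model An `fda_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fda_json <- function(model, path) {
  stopifnot(inherits(model, "fda_model"))
  obj <- list(
    subset = model$subset,
    w = unname(model$w),
    normalization = list(measure = model$params$measure,
                         mean = model$params$mean, sd = model$params$sd),
    orientation = "ASD_positive",
    t_asd = unname(model$t_asd), t_td = unname(model$t_td),
    j = model$j, c_statistic = model$c_statistic,
    degenerate = model$degenerate
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fda_json
#' @export
read_fda_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- structure(
    tibble(measure = obj$normalization$measure,
           mean = obj$normalization$mean, sd = obj$normalization$sd),
    class = c("zscore_params", "tbl_df", "tbl", "data.frame")
  )
  w <- setNames(obj$w, obj$subset)
  structure(
    list(subset = obj$subset, w = w, params = params,
         t_asd = obj$t_asd, t_td = obj$t_td,
         j = obj$j, c_statistic = obj$c_statistic,
         degenerate = isTRUE(obj$degenerate)),
    class = "fda_model"
  )
}
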