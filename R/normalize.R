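#' Fit z-score normalization parameters on training samples
#'
#' Estimates per-measure mean and standard deviation on a training table so
#' that applying them yields columns with mean zero and standard deviation
#' one across the training samples. Validation or trial samples are later
#' normalized with these same training parameters — never their own moments —
#' to keep model assessment free of information leakage.
#'
#' The sample (n - 1 denominator) standard deviation is used.
#'
#' @param data Training data frame.
#' @param measures Columns to normalize (default: every canonical measure
#'   present in `data`).
#' @return An object of class `zscore_params`: a tibble with columns
#'   `measure`, `mean`, `sd`.
#' @export
#' @examples
#' params <- zscore_fit(tibble::tibble(a = c(1, 3), b = c(0, 10)))
#' zscore_apply(tibble::tibble(a = 2, b = 5), params)
zscore_fit <- function(data, measures = NULL) {
  data <- as_tibble(data)
  if (is.null(measures)) {
    measures <- intersect(focm_measures(), names(data))
    if (length(measures) == 0) {
      measures <- names(data)[vapply(data, is.numeric, logical(1))]
    }
  }
  missing_cols <- setdiff(measures, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) < 2) abort("need at least 2 training samples to normalize")
  mu <- vapply(measures, function(m) mean(data[[m]]), numeric(1))
  sigma <- vapply(measures, function(m) sd(data[[m]]), numeric(1))
  zero <- which(!is.finite(sigma) | sigma <= 0)
  if (length(zero) > 0) {
    abort(paste0("constant training column(s) cannot be normalized: ",
                 paste(measures[zero], collapse = ", ")))
  }
  structure(
    tibble(measure = measures, mean = unname(mu), sd = unname(sigma)),
    class = c("zscore_params", "tbl_df", "tbl", "data.frame")
  )
}

#' Apply frozen z-score normalization parameters
#'
#' @param data Data frame whose measure columns are a subset of the fitted
#'   parameters.
#' @param params A `zscore_params` object from [zscore_fit()].
#' @param measures Columns to transform (default: all columns named in
#'   `params` that are present in `data`; every measure column in `data`
#'   must be covered by `params`).
#' @return `data` with the selected columns replaced by
#'   `(x - mean) / sd` using the training parameters.
#' @export
zscore_apply <- function(data, params, measures = NULL) {
  stopifnot(inherits(params, "zscore_params"))
  data <- as_tibble(data)
  if (is.null(measures)) {
    measures <- intersect(params$measure, names(data))
  }
  unknown <- setdiff(measures, params$measure)
  if (length(unknown) > 0) {
    abort(paste0("no normalization parameters for: ",
                 paste(unknown, collapse = ", ")))
  }
  missing_cols <- setdiff(measures, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  idx <- match(measures, params$measure)
  for (j in seq_along(measures)) {
    m <- measures[j]
    data[[m]] <- (data[[m]] - params$mean[idx[j]]) / params$sd[idx[j]]
  }
  data
}
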