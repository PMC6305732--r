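#' Enumerate all measurement subsets of a given size
#'
#' All \eqn{\binom{m}{k}} distinct size-`k` subsets of a measure panel, in
#' lexicographic order with respect to the canonical measure order. With the
#' full 15-measure panel there are 3003 five-variable and 5005 six-variable
#' subsets.
#'
#' @param measures Either the panel as a character vector (canonical order)
#'   or a single integer `m`, in which case the first `m` canonical measures
#'   are used (indices when `m` exceeds the canonical panel).
#' @param k Subset size, `1 <= k <= m`.
#' @return A list of length `choose(m, k)`; each element a length-`k`
#'   vector of measure names (or indices).
#' @export
#' @examples
#' length(enumerate_subsets(15, 5)) # 3003
enumerate_subsets <- function(measures, k) {
  if (is.numeric(measures) && length(measures) == 1) {
    m <- as.integer(measures)
    measures <- if (m <= length(focm_measures())) {
      focm_measures()[seq_len(m)]
    } else {
      seq_len(m)
    }
  }
  m <- length(measures)
  if (k < 1 || k > m) {
    abort(paste0("subset size k = ", k, " must be between 1 and m = ", m))
  }
  idx <- combn(m, k, simplify = FALSE) # lexicographic in index order
  lapply(idx, function(i) measures[i])
}

subset_id <- function(subset) paste(subset, collapse = "+")

#' Exhaustive discriminant-model subset search
#'
#' Fits a Fisher discriminant model on every size-`k` subset of the panel
#' and scores each by the C-statistic of the fitted discriminant scores
#' (the selection criterion; cross-validation is applied only to the chosen
#' model afterwards). Subsets whose within-class scatter is singular beyond
#' regularization are scored 0.5 and flagged rather than dropped, keeping
#' the sweep total.
#'
#' @param data Cohort data frame with `cohort` and measure columns.
#' @param k Subset size.
#' @param measures Candidate measures (default: canonical measures present).
#' @return A tibble of class `subset_search` with columns `subset`
#'   (list-column), `subset_id`, `k`, `criterion` (`"c_statistic"`),
#'   `value`, `degenerate`; sorted by decreasing value, ties broken by
#'   enumeration (lexicographic) order.
#' @export
search_fda <- function(data, k, measures = NULL) {
  data <- as_tibble(data)
  if (is.null(measures)) measures <- intersect(focm_measures(), names(data))
  params <- zscore_fit(data, measures)
  norm <- zscore_apply(data, params, measures)
  x_full <- as.matrix(norm[, measures, drop = FALSE])
  is_asd <- norm$cohort == "ASD"
  subsets <- enumerate_subsets(measures, k)
  rows <- purrr::map(subsets, function(s) {
    res <- tryCatch(
      suppressWarnings(fda_direction(x_full[, s, drop = FALSE], is_asd)),
      error = function(e) NULL
    )
    if (is.null(res) || res$degenerate) {
      tibble(value = 0.5, degenerate = TRUE)
    } else {
      tibble(value = c_statistic(res$t_asd, res$t_td), degenerate = FALSE)
    }
  })
  out <- bind_rows(rows)
  out$subset <- subsets
  out$subset_id <- vapply(subsets, subset_id, character(1))
  out$k <- k
  out$criterion <- "c_statistic"
  out <- out[order(-out$value), c("subset", "subset_id", "k", "criterion",
                                  "value", "degenerate")]
  structure(out, class = c("subset_search", class(tibble())),
            measures = measures)
}

#' Exhaustive kernel-PLS subset search
#'
#' Scores every size-`k` predictor subset by leave-one-out cross-validated
#' \eqn{R^2} — the criterion appropriate for the regression task, where
#' fitted \eqn{R^2} would reward overfitting.
#'
#' @param data Change table (e.g. from [delta_table()]).
#' @param k Subset size.
#' @param predictors Candidate predictor columns (default: canonical
#'   measures present).
#' @param response Response column (default `"dvabs"`).
#' @param components,width,kernel Passed to [loo_kpls()]; fixing
#'   `components` avoids the per-subset inner selection sweep.
#' @return A tibble of class `subset_search` with `criterion = "cv_r2"`,
#'   sorted by decreasing value.
#' @export
search_kpls <- function(data, k, predictors = NULL, response = "dvabs",
                        components = NULL, width = NULL,
                        kernel = c("gaussian", "linear")) {
  kernel <- match.arg(kernel)
  data <- as_tibble(data)
  if (is.null(predictors)) {
    predictors <- intersect(focm_measures(), names(data))
  }
  subsets <- enumerate_subsets(predictors, k)
  values <- vapply(subsets, function(s) {
    tryCatch(
      loo_r2(data, s, response, components = components, width = width,
             kernel = kernel),
      error = function(e) NA_real_
    )
  }, numeric(1))
  out <- tibble(
    subset = subsets,
    subset_id = vapply(subsets, subset_id, character(1)),
    k = k, criterion = "cv_r2",
    value = values,
    degenerate = !is.finite(values)
  )
  out$value[out$degenerate] <- -Inf
  out <- out[order(-out$value), ]
  structure(out, class = c("subset_search", class(tibble())),
            measures = predictors)
}

#' Best criterion value for each subset size
#'
#' Runs the exhaustive discriminant search for each size in `ks` and keeps
#' the maximum criterion value per size — the curve used to pick the
#' smallest panel giving satisfactory separation.
#'
#' @param data Cohort data frame.
#' @param ks Vector of subset sizes.
#' @param measures Candidate measures.
#' @return A tibble with `k`, `best_value`, `best_subset_id`.
#' @export
best_by_size <- function(data, ks, measures = NULL) {
  rows <- purrr::map(ks, function(k) {
    res <- search_fda(data, k, measures)
    tibble(k = k, best_value = res$value[1], best_subset_id = res$subset_id[1])
  })
  bind_rows(rows)
}

#' Appearance frequency of measures among top-scoring subsets
#'
#' Among the subsets whose criterion value is at least `threshold`, the
#' percentage in which each measure appears — the variable-importance view
#' used to judge which measurements matter beyond the single best model.
#'
#' @param results A `subset_search` tibble.
#' @param threshold Criterion cutoff; subsets with `value >= threshold`
#'   qualify.
#' @return A tibble of class `frequency_report` with columns `measure`,
#'   `n_models`, `pct` (in \[0, 100\]), covering every candidate measure of
#'   the search; attributes `threshold` and `n_qualifying`.
#' @export
frequency_analysis <- function(results, threshold) {
  if (nrow(results) == 0) abort("empty result set")
  measures <- attr(results, "measures") %||%
    sort(unique(unlist(results$subset)))
  qual <- results[results$value >= threshold, ]
  n_qual <- nrow(qual)
  if (n_qual == 0) {
    abort(paste0("no model meets the criterion threshold ", threshold))
  }
  counts <- unname(vapply(measures, function(m) {
    sum(vapply(qual$subset, function(s) m %in% s, logical(1)))
  }, numeric(1)))
  out <- tibble(
    measure = measures,
    n_models = as.integer(counts),
    pct = 100 * counts / n_qual
  )
  structure(out, class = c("frequency_report", class(tibble())),
            threshold = threshold, n_qualifying = n_qual)
}
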