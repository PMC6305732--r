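#' Canonical FOCM/TS measure names
#'
#' The analysis operates on a fixed panel of 15 plasma measurements spanning
#' the folate-dependent one-carbon metabolism (FOCM) pathway (methylation arm)
#' and the transsulfuration (TS) pathway (glutathione/redox arm). Eleven are
#' raw concentrations; four are derived from them: the SAM/SAH ratio (an
#' indicator of DNA methylation capacity), the tGSH/GSSG and fGSH/GSSG redox
#' ratios, and the percent oxidized glutathione fraction
#' \eqn{2\,\mathrm{GSSG} / (\mathrm{tGSH} + 2\,\mathrm{GSSG})}.
#'
#' Column names are snake_case identifiers: `methionine`, `sam`, `sah`,
#' `sam_sah`, `homocysteine`, `adenosine`, `cysteine`, `glu_cys`, `cys_gly`,
#' `tgsh`, `fgsh`, `gssg`, `tgsh_gssg`, `fgsh_gssg`, `pct_oxidized`.
#' `pct_oxidized` is stored as a fraction in \[0, 1\].
#'
#' @return A character vector of measure names in canonical order.
#' @export
#' @examples
#' focm_measures()
focm_measures <- function() {
  c(
    "methionine", "sam", "sah", "sam_sah", "homocysteine", "adenosine",
    "cysteine", "glu_cys", "cys_gly", "tgsh", "fgsh", "gssg",
    "tgsh_gssg", "fgsh_gssg", "pct_oxidized"
  )
}

#' @rdname focm_measures
#' @export
focm_raw_measures <- function() {
  setdiff(focm_measures(), focm_derived_measures())
}

#' @rdname focm_measures
#' @export
focm_derived_measures <- function() {
  c("sam_sah", "tgsh_gssg", "fgsh_gssg", "pct_oxidized")
}

# numerator/denominator wiring for each derived measure
derived_measure_spec <- function() {
  list(
    sam_sah      = list(num = "sam",  den = "sah"),
    tgsh_gssg    = list(num = "tgsh", den = "gssg"),
    fgsh_gssg    = list(num = "fgsh", den = "gssg"),
    pct_oxidized = list(num = NULL,   den = NULL) # 2*gssg / (tgsh + 2*gssg)
  )
}

compute_derived <- function(data, measure) {
  switch(measure,
    sam_sah      = data$sam / data$sah,
    tgsh_gssg    = data$tgsh / data$gssg,
    fgsh_gssg    = data$fgsh / data$gssg,
    pct_oxidized = 2 * data$gssg / (data$tgsh + 2 * data$gssg),
    abort(paste0("unknown derived measure '", measure, "'"))
  )
}

#' Fill in derived ratio measures from raw concentrations
#'
#' Computes `sam_sah`, `tgsh_gssg`, `fgsh_gssg` and `pct_oxidized` from the
#' raw concentration columns, leaving the raw columns unchanged. If a derived
#' column is already present its values are validated against recomputation
#' and, on disagreement beyond `tol` (relative), the row is rejected with an
#' error; this prevents silent inconsistency between raw and derived columns.
#' The operation is idempotent on already-derived tables.
#'
#' @param data A data frame with the raw concentration columns needed by the
#'   requested derived measures (see [focm_measures()]).
#' @param measures Character vector of derived measures to compute. Defaults
#'   to all four.
#' @param tol Relative tolerance for validating pre-existing derived columns.
#' @return A tibble with the derived columns filled (placed in canonical
#'   order after any identifier columns).
#' @export
#' @examples
#' derive_ratios(tibble::tibble(
#'   methionine = 25, sam = 90, sah = 20, homocysteine = 6, adenosine = 0.3,
#'   cysteine = 200, glu_cys = 2, cys_gly = 40, tgsh = 2, fgsh = 1.6, gssg = 1
#' ))
derive_ratios <- function(data, measures = focm_derived_measures(),
                          tol = 1e-6) {
  data <- as_tibble(data)
  measures <- match.arg(measures, focm_derived_measures(),
                        several.ok = TRUE)
  spec <- derived_measure_spec()

  needed_raw <- unique(unlist(lapply(measures, function(m) {
    if (m == "pct_oxidized") c("tgsh", "gssg") else unlist(spec[[m]])
  })))
  missing_raw <- setdiff(needed_raw, names(data))
  if (length(missing_raw) > 0) {
    abort(paste0("missing raw measure column(s): ",
                 paste(missing_raw, collapse = ", ")))
  }
  for (m in needed_raw) {
    bad <- which(!is.na(data[[m]]) & data[[m]] < 0)
    if (length(bad) > 0) {
      abort(paste0("negative values in raw measure '", m, "' (row ",
                   bad[1], "); concentrations must be >= 0"))
    }
  }

  for (m in measures) {
    if (m == "pct_oxidized") {
      den <- data$tgsh + 2 * data$gssg
      if (any(den <= 0, na.rm = TRUE)) {
        abort("zero denominator for 'pct_oxidized': tgsh + 2*gssg must be > 0")
      }
    } else {
      dcol <- spec[[m]]$den
      if (any(data[[dcol]] <= 0, na.rm = TRUE)) {
        abort(paste0("zero denominator for '", m, "': '", dcol,
                     "' must be > 0"))
      }
    }
    value <- compute_derived(data, m)
    if (m %in% names(data)) {
      old <- data[[m]]
      ok <- is.na(old) | abs(old - value) <= tol * pmax(abs(value), 1e-12)
      if (!all(ok)) {
        abort(paste0("derived column '", m, "' disagrees with recomputation ",
                     "from raw measures beyond relative tolerance ",
                     format(tol), " (row ", which(!ok)[1], ")"))
      }
    }
    data[[m]] <- value
  }

  id_cols <- setdiff(names(data), focm_measures())
  panel_cols <- intersect(focm_measures(), names(data))
  data[, c(id_cols, panel_cols)]
}

#' Average two time points of a metabolite panel
#'
#' Element-wise arithmetic mean of the raw concentrations of two complete
#' panels measured at different time points, with the derived ratios
#' recomputed from the averaged concentrations (not averaged themselves),
#' so the returned panel keeps the algebraic invariants of the measure set.
#' Used when a trial measures metabolites at two follow-up times that must be
#' collapsed to one (e.g. 8- and 16-week panels averaged to a 12-week
#' estimate).
#'
#' @param panel_a,panel_b Data frames with identical measure columns (the
#'   full 15-measure panel) and, if present, matching `participant_id`
#'   columns in the same order.
#' @return A tibble of the same shape with averaged raw concentrations and
#'   re-derived ratios.
#' @export
average_timepoints <- function(panel_a, panel_b) {
  panel_a <- as_tibble(panel_a)
  panel_b <- as_tibble(panel_b)
  meas_a <- intersect(focm_measures(), names(panel_a))
  meas_b <- intersect(focm_measures(), names(panel_b))
  if (!setequal(meas_a, meas_b)) {
    abort("panels carry different measure sets and cannot be averaged")
  }
  if (!setequal(focm_measures(), meas_a)) {
    abort(paste0("incomplete panel: missing ",
                 paste(setdiff(focm_measures(), meas_a), collapse = ", ")))
  }
  if (nrow(panel_a) != nrow(panel_b)) {
    abort("panels have different numbers of rows")
  }
  if ("participant_id" %in% names(panel_a) &&
      "participant_id" %in% names(panel_b) &&
      !identical(panel_a$participant_id, panel_b$participant_id)) {
    abort("participant_id mismatch between the two time points")
  }
  out <- panel_a
  for (m in focm_raw_measures()) {
    out[[m]] <- (panel_a[[m]] + panel_b[[m]]) / 2
  }
  for (m in focm_derived_measures()) {
    out[[m]] <- NULL
  }
  derive_ratios(out)
}

# validates a cohort/panel table: completeness, non-negativity, ratio
# consistency; drops incomplete rows with a message. Returns the tibble.
validate_panel_table <- function(data, measures = focm_measures(),
                                 drop_incomplete = TRUE) {
  data <- as_tibble(data)
  missing_cols <- setdiff(measures, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing measurement column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  complete <- stats::complete.cases(data[, measures])
  if (!all(complete)) {
    if (!drop_incomplete) abort("incomplete measurement rows present")
    inform(paste0("excluding ", sum(!complete),
                  " row(s) with incomplete panels"))
    data <- data[complete, ]
  }
  derive_ratios(data)
}

#' Read a case-control cohort table from CSV
#'
#' Expects a comma-delimited file with a header row carrying
#' `participant_id`, `cohort` (values `ASD` or `TD`) and the 15 canonical
#' measure columns ([focm_measures()]); `pct_oxidized` is stored as a
#' fraction in \[0, 1\]. Rows with an incomplete panel are excluded with a
#' message, mirroring the completeness inclusion criterion of case-control
#' metabolomics studies. Derived ratio columns are validated against
#' recomputation from the raw concentrations.
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per retained participant.
#' @export
read_cohort_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("participant_id", "cohort")) {
    if (!col %in% names(data)) {
      abort(paste0("cohort file is missing required column '", col, "'"))
    }
  }
  bad <- setdiff(unique(data$cohort), c("ASD", "TD"))
  if (length(bad) > 0) {
    abort(paste0("cohort labels must be 'ASD' or 'TD'; found: ",
                 paste(bad, collapse = ", ")))
  }
  validate_panel_table(data)
}

#' Read a paired pre/post treatment-trial table from CSV
#'
#' Expects a comma-delimited file with `participant_id`, optionally `arm`,
#' the 15 canonical measure columns prefixed `pre_` and `post_`, and
#' `pre_vabs` / `post_vabs` (Vineland Adaptive Behavior Scales Composite
#' scores). Rows missing any of these are excluded with a message,
#' mirroring the requirement of complete pre- and post-treatment panels
#' plus behavior scores. Derived ratio columns in each time point are
#' validated against recomputation.
#'
#' @param path Path to the CSV file.
#' @param arm Optional arm label to attach (overrides any `arm` column).
#' @return A tibble with one row per retained participant.
#' @export
read_trial_csv <- function(path, arm = NULL) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"participant_id" %in% names(data)) {
    abort("trial file is missing required column 'participant_id'")
  }
  required <- c(paste0("pre_", focm_measures()), paste0("post_", focm_measures()),
                "pre_vabs", "post_vabs")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("trial file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  complete <- stats::complete.cases(data[, required])
  if (!all(complete)) {
    inform(paste0("excluding ", sum(!complete),
                  " row(s) with incomplete pre/post panels or VABS scores"))
    data <- data[complete, ]
  }
  for (prefix in c("pre_", "post_")) {
    sub <- data[, paste0(prefix, focm_measures())]
    names(sub) <- focm_measures()
    derive_ratios(sub) # validates; result discarded
  }
  if (!is.null(arm)) data$arm <- arm
  as_tibble(data)
}

#' Pre-to-post change table for regression
#'
#' Collapses a paired trial table to per-participant changes: one column per
#' selected measure holding post minus pre, plus `dvabs`, the change in the
#' VABS Composite score (the regression response).
#'
#' @param trial A trial tibble as returned by [read_trial_csv()] or
#'   [generate_trial()].
#' @param measures Measures to difference (default: all 15).
#' @return A tibble with `participant_id` and `arm` (if present) followed by
#'   one column per measure holding its post-minus-pre change, and `dvabs`.
#' @export
delta_table <- function(trial, measures = focm_measures()) {
  trial <- as_tibble(trial)
  required <- c(paste0("pre_", measures), paste0("post_", measures),
                "pre_vabs", "post_vabs")
  missing_cols <- setdiff(required, names(trial))
  if (length(missing_cols) > 0) {
    abort(paste0("trial table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- trial[, intersect(c("participant_id", "arm"), names(trial))]
  for (m in measures) {
    out[[m]] <- trial[[paste0("post_", m)]] - trial[[paste0("pre_", m)]]
  }
  out$dvabs <- trial$post_vabs - trial$pre_vabs
  as_tibble(out)
}
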