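#' Silverman rule-of-thumb bandwidth
#'
#' \eqn{h = 0.9 \min(\hat\sigma, \mathrm{IQR}/1.34)\, n^{-1/5}}, the standard
#' default for a univariate Gaussian kernel. When the interquartile range is
#' zero (heavily tied scores) the standard deviation alone is used; a score
#' set with zero spread has no data-driven bandwidth and requires an explicit
#' one.
#'
#' @param scores Numeric vector of discriminant scores.
#' @return Bandwidth in score units.
#' @export
silverman_bw <- function(scores) {
  n <- length(scores)
  if (n < 2) abort("need >= 2 scores for a data-driven bandwidth; pass `bandwidth` explicitly")
  s <- sd(scores)
  iqr <- stats::IQR(scores)
  spread <- if (iqr > 0) min(s, iqr / 1.34) else s
  if (!is.finite(spread) || spread <= 0) {
    abort("scores have zero spread; pass `bandwidth` explicitly")
  }
  0.9 * spread * n^(-1 / 5)
}

#' Gaussian kernel density estimate of a score set
#'
#' Places an equal-weight Gaussian kernel on each reference score and
#' tabulates the mixture on a fixed evaluation grid. The tabulated density
#' is renormalized to unit trapezoidal mass over the grid, removing
#' truncation bias at the grid edges, so that all probability masses
#' computed from the model are deterministic functions of the grid.
#'
#' @param scores Reference scores (finite, length >= 1).
#' @param bandwidth Kernel bandwidth in score units; default
#'   [silverman_bw()] of `scores`.
#' @param grid Evaluation grid (ordered, equally spaced). Default: `grid_n`
#'   points spanning `range(scores)` extended by 4 bandwidths on each side.
#' @param grid_n Number of grid points when `grid` is built here.
#' @return An object of class `kde_model`: list with `scores`, `bandwidth`,
#'   `grid`, `density` (renormalized) and `cdf` (trapezoidal, 0 at the first
#'   grid point, 1 at the last).
#' @export
fit_kde <- function(scores, bandwidth = NULL, grid = NULL, grid_n = 2048) {
  scores <- as.numeric(scores)
  if (length(scores) == 0) abort("empty score set")
  if (any(!is.finite(scores))) abort("scores must be finite")
  if (is.null(bandwidth)) bandwidth <- silverman_bw(scores)
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    abort("bandwidth must be a positive number")
  }
  if (is.null(grid)) {
    lo <- min(scores) - 4 * bandwidth
    hi <- max(scores) + 4 * bandwidth
    grid <- seq(lo, hi, length.out = grid_n)
  }
  if (is.unsorted(grid, strictly = TRUE)) abort("grid must be strictly increasing")
  dens <- vapply(grid, function(g) {
    mean(stats::dnorm(g, mean = scores, sd = bandwidth))
  }, numeric(1))
  dx <- diff(grid)
  mass <- sum(dx * (dens[-1] + dens[-length(dens)]) / 2)
  if (mass <= 0) abort("density has zero mass on the grid")
  dens <- dens / mass
  cdf <- c(0, cumsum(dx * (dens[-1] + dens[-length(dens)]) / 2))
  structure(
    list(scores = scores, bandwidth = bandwidth, grid = grid,
         density = dens, cdf = cdf),
    class = "kde_model"
  )
}

#' Density estimates of two score sets on a shared grid
#'
#' Builds one evaluation grid spanning the pooled range of both score sets,
#' extended by 4 bandwidths (the larger of the two Silverman bandwidths)
#' on each side, and fits both kernel density estimates on it. A shared grid
#' is required by [find_threshold()].
#'
#' @param td_scores,asd_scores Reference score sets for the TD and ASD
#'   cohorts.
#' @param bandwidth_td,bandwidth_asd Optional explicit bandwidths.
#' @param grid_n Number of grid points (default 2048).
#' @return A list with `kde_model` elements `td` and `asd`.
#' @export
fit_kde_pair <- function(td_scores, asd_scores,
                         bandwidth_td = NULL, bandwidth_asd = NULL,
                         grid_n = 2048) {
  if (is.null(bandwidth_td)) bandwidth_td <- silverman_bw(td_scores)
  if (is.null(bandwidth_asd)) bandwidth_asd <- silverman_bw(asd_scores)
  pad <- 4 * max(bandwidth_td, bandwidth_asd)
  pooled <- range(c(td_scores, asd_scores))
  grid <- seq(pooled[1] - pad, pooled[2] + pad, length.out = grid_n)
  list(
    td = fit_kde(td_scores, bandwidth = bandwidth_td, grid = grid),
    asd = fit_kde(asd_scores, bandwidth = bandwidth_asd, grid = grid)
  )
}

# linear-interpolated trapezoidal CDF at arbitrary thresholds
kde_cdf_at <- function(model, threshold) {
  grid <- model$grid
  n <- length(grid)
  vapply(threshold, function(th) {
    if (th <= grid[1]) return(0)
    if (th >= grid[n]) return(1)
    i <- findInterval(th, grid)
    frac <- (th - grid[i]) / (grid[i + 1] - grid[i])
    d_at <- model$density[i] + frac * (model$density[i + 1] - model$density[i])
    model$cdf[i] + (th - grid[i]) * (model$density[i] + d_at) / 2
  }, numeric(1))
}

#' Probability mass of a density model on one side of a threshold
#'
#' Renormalized trapezoidal mass below or above a score threshold, with
#' linear interpolation of the tabulated density between grid points.
#' Thresholds beyond the grid give 0 or 1; the two sides always sum to 1.
#'
#' @param model A `kde_model`.
#' @param threshold Score threshold(s).
#' @param side `"below"` or `"above"`.
#' @return Probability mass in \[0, 1\].
#' @export
tail_mass <- function(model, threshold, side = c("below", "above")) {
  stopifnot(inherits(model, "kde_model"))
  side <- match.arg(side)
  below <- kde_cdf_at(model, threshold)
  if (side == "below") below else 1 - below
}

#' Balanced-error classification threshold from two score densities
#'
#' Under the null hypothesis that a participant is TD, the Type I (false
#' positive) error at a threshold \eqn{\theta} is the TD density mass above
#' \eqn{\theta}, and the Type II (false negative) error is the ASD density
#' mass below it (ASD scores lie on the positive side by the model's
#' orientation convention). The threshold is placed at the grid point where
#' the absolute difference between the two errors is smallest, balancing
#' them; when several grid points tie, the median tied point is taken (lower
#' middle for an even tie count), keeping the choice deterministic.
#'
#' @param td A `kde_model` of the TD reference scores.
#' @param asd A `kde_model` of the ASD reference scores, on the same grid.
#' @return An object of class `threshold_model`: list with the two models
#'   (`td`, `asd`), the threshold `h0`, and the balanced errors `type1`,
#'   `type2` at `h0`.
#' @export
find_threshold <- function(td, asd) {
  stopifnot(inherits(td, "kde_model"), inherits(asd, "kde_model"))
  if (length(td$grid) != length(asd$grid) ||
      max(abs(td$grid - asd$grid)) > 1e-9 * max(1, max(abs(td$grid)))) {
    abort("the two density models must share a common grid (see fit_kde_pair)")
  }
  type1 <- 1 - td$cdf   # TD mass above theta
  type2 <- asd$cdf      # ASD mass below theta
  gap <- abs(type1 - type2)
  ties <- which(gap == min(gap))
  idx <- ties[ceiling(length(ties) / 2)]
  structure(
    list(td = td, asd = asd, h0 = td$grid[idx],
         type1 = type1[idx], type2 = type2[idx]),
    class = "threshold_model"
  )
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("Balanced-error score threshold\n")
  cat(sprintf("  H0 threshold = %.4f\n", x$h0))
  cat(sprintf("  Type I error  = %.3f (TD mass above H0)\n", x$type1))
  cat(sprintf("  Type II error = %.3f (ASD mass below H0)\n", x$type2))
  cat(sprintf("  bandwidths: TD %.4f, ASD %.4f\n",
              x$td$bandwidth, x$asd$bandwidth))
  invisible(x)
}

#' @export
tidy.threshold_model <- function(x, ...) {
  tibble(
    h0 = x$h0, type1 = x$type1, type2 = x$type2,
    bandwidth_td = x$td$bandwidth, bandwidth_asd = x$asd$bandwidth,
    grid_n = length(x$td$grid),
    grid_min = x$td$grid[1], grid_max = x$td$grid[length(x$td$grid)]
  )
}

#' Serialize a threshold report to JSON
#'
#' Records the bandwidths, grid specification, threshold and balanced
#' Type I/II errors for auditability of downstream shift reports.
#'
#' @param x A `threshold_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_threshold_json <- function(x, path) {
  stopifnot(inherits(x, "threshold_model"))
  jsonlite::write_json(as.list(tidy(x)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
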