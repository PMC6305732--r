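#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a synthetic case-control study and
#' its treatment arms, standing in for clinical FOCM/TS panel data that are
#' not publicly deposited. Raw concentrations are multivariate log-normal
#' (metabolite levels are non-negative and right-skewed); the four ratio
#' measures are always derived from the sampled raw concentrations, never
#' sampled themselves, so every generated table satisfies the panel's
#' algebraic invariants. The ASD cohort's log-mean vector is offset from the
#' TD vector with the redox measures (GSSG, and hence percent oxidized
#' glutathione) separating more strongly than the methylation measures.
#' Treatment moves each participant's log-concentrations a configurable
#' fraction of the way from the ASD mean toward the TD mean, plus
#' participant-level noise; the change in VABS Composite is a linear (or
#' optionally mildly quadratic) combination of standardized metabolite
#' changes plus Gaussian noise scaled so the link explains a target fraction
#' `link_r2` of the response variance.
#'
#' @param n_asd,n_td Case-control cohort sizes (defaults 92 and 82).
#' @param arms Named integer vector of treatment-arm sizes (defaults:
#'   MeCbl + low-dose folinic acid 33, BH4 8, high-dose folinic acid 14,
#'   placebo 19).
#' @param shift Named vector (same names as `arms`): fraction of the
#'   ASD-to-TD log-mean difference each arm's treatment applies.
#' @param log_mean_td Named log-scale mean vector for the 11 raw measures
#'   in the TD cohort.
#' @param asd_offset Named log-scale offsets added for the ASD cohort.
#' @param log_sd Named log-scale standard deviations.
#' @param within_block_cor,between_block_cor Correlations within the
#'   methylation and thiol blocks and across them.
#' @param tgsh_fgsh_cor Correlation between total and free glutathione.
#' @param trial_noise_sd Log-scale sd of the participant-level noise added
#'   to post-treatment concentrations.
#' @param link_coefs Named coefficients of the behavior link over
#'   standardized metabolite changes.
#' @param link_r2 Target fraction of response variance explained by the
#'   link (noise is scaled to match); ignored when `vabs_noise_sd` is set.
#' @param link_nonlinear If `TRUE`, a quadratic term bends the link.
#' @param vabs_noise_sd Optional fixed response noise sd (VABS points).
#' @param vabs_baseline_mean,vabs_baseline_sd Pre-treatment VABS Composite
#'   distribution.
#' @param seed Integer seed; the single source of randomness for all draws.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_asd = 92, n_td = 82,
                          arms = c(mecbl_ldfa = 33, bh4 = 8,
                                   hdfa = 14, placebo = 19),
                          shift = c(mecbl_ldfa = 0.8, bh4 = 0.7,
                                    hdfa = 0.3, placebo = 0.1),
                          log_mean_td = NULL, asd_offset = NULL,
                          log_sd = NULL,
                          within_block_cor = 0.3, between_block_cor = 0.1,
                          tgsh_fgsh_cor = 0.75,
                          trial_noise_sd = 0.08,
                          link_coefs = c(tgsh = 1, gssg = -1.2,
                                         methionine = 0.6),
                          link_r2 = 0.5, link_nonlinear = FALSE,
                          vabs_noise_sd = NULL,
                          vabs_baseline_mean = 70, vabs_baseline_sd = 8,
                          seed = 1) {
  raw <- focm_raw_measures()
  default_mean <- c(
    methionine = 3.22, sam = 4.50, sah = 3.00, homocysteine = 1.79,
    adenosine = -1.20, cysteine = 5.35, glu_cys = 0.69, cys_gly = 3.69,
    tgsh = 0.79, fgsh = 0.59, gssg = -1.90
  )
  default_offset <- c(
    methionine = -0.10, sam = -0.04, sah = 0.06, homocysteine = 0.04,
    adenosine = 0.05, cysteine = -0.06, glu_cys = -0.03, cys_gly = -0.05,
    tgsh = -0.14, fgsh = -0.14, gssg = 0.32
  )
  log_mean_td <- fill_named(log_mean_td, default_mean, raw)
  asd_offset <- fill_named(asd_offset, default_offset, raw)
  log_sd <- fill_named(log_sd, setNames(rep(0.20, length(raw)), raw), raw)
  if (any(log_sd <= 0)) abort("log_sd values must be positive")
  if (any(c(n_asd, n_td, arms) < 1)) abort("cohort and arm sizes must be >= 1")
  if (!setequal(names(arms), names(shift))) {
    abort("arms and shift must carry the same arm names")
  }
  if (trial_noise_sd < 0) abort("trial_noise_sd must be >= 0")
  unknown <- setdiff(names(link_coefs), focm_measures())
  if (length(unknown) > 0) {
    abort(paste0("link_coefs names not in the panel: ",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- structure(
    list(n_asd = n_asd, n_td = n_td, arms = arms, shift = shift,
         log_mean_td = log_mean_td, asd_offset = asd_offset, log_sd = log_sd,
         within_block_cor = within_block_cor,
         between_block_cor = between_block_cor,
         tgsh_fgsh_cor = tgsh_fgsh_cor,
         trial_noise_sd = trial_noise_sd,
         link_coefs = link_coefs, link_r2 = link_r2,
         link_nonlinear = link_nonlinear, vabs_noise_sd = vabs_noise_sd,
         vabs_baseline_mean = vabs_baseline_mean,
         vabs_baseline_sd = vabs_baseline_sd,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
  cfg$sigma <- build_log_covariance(cfg)
  cfg
}

fill_named <- function(user, default, names_needed) {
  out <- default
  if (!is.null(user)) {
    unknown <- setdiff(names(user), names_needed)
    if (length(unknown) > 0) {
      abort(paste0("unknown measure(s): ", paste(unknown, collapse = ", ")))
    }
    out[names(user)] <- user
  }
  missing_names <- setdiff(names_needed, names(out))
  if (length(missing_names) > 0) {
    abort(paste0("missing value(s) for: ",
                 paste(missing_names, collapse = ", ")))
  }
  out[names_needed]
}

# block-structured log-scale covariance; validated positive definite
build_log_covariance <- function(cfg) {
  raw <- focm_raw_measures()
  methyl <- c("methionine", "sam", "sah", "homocysteine", "adenosine")
  r <- matrix(cfg$between_block_cor, length(raw), length(raw),
              dimnames = list(raw, raw))
  thiol <- setdiff(raw, methyl)
  r[methyl, methyl] <- cfg$within_block_cor
  r[thiol, thiol] <- cfg$within_block_cor
  r["tgsh", "fgsh"] <- r["fgsh", "tgsh"] <- cfg$tgsh_fgsh_cor
  diag(r) <- 1
  sigma <- diag(cfg$log_sd) %*% r %*% diag(cfg$log_sd)
  dimnames(sigma) <- list(raw, raw)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    abort("log-scale covariance is not positive definite; adjust correlations")
  }
  sigma
}

draw_lognormal <- function(n, mu, sigma) {
  x <- exp(MASS::mvrnorm(n, mu = mu, Sigma = sigma))
  if (n == 1) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(mu)))
  as_tibble(as.data.frame(x))
}

#' Generate a synthetic case-control cohort table
#'
#' Draws raw concentrations from cohort-specific multivariate log-normal
#' distributions and derives the ratio measures, yielding a table with the
#' same shape and invariants as a real case-control panel file.
#'
#' @param config A [cohort_config()].
#' @param seed Optional seed override (default `config$seed`).
#' @return A cohort tibble (`participant_id`, `cohort`, 15 measures).
#' @export
generate_case_control <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- seed %||% config$seed
  mu_td <- config$log_mean_td
  mu_asd <- mu_td + config$asd_offset
  withr::with_seed(seed, {
    asd <- draw_lognormal(config$n_asd, mu_asd, config$sigma)
    td <- draw_lognormal(config$n_td, mu_td, config$sigma)
    asd$cohort <- "ASD"
    td$cohort <- "TD"
    out <- bind_rows(asd, td)
    out$participant_id <- sprintf("S%03d", seq_len(nrow(out)))
    derive_ratios(out)
  })
}

# paired pre/post panels for one arm, without behavior scores
gen_trial_panels <- function(config, arm, seed) {
  n <- config$arms[[arm]]
  mu_td <- config$log_mean_td
  mu_asd <- mu_td + config$asd_offset
  shift_vec <- config$shift[[arm]] * (mu_td - mu_asd)
  raw <- focm_raw_measures()
  withr::with_seed(seed, {
    pre_log <- MASS::mvrnorm(n, mu = mu_asd, Sigma = config$sigma)
    if (n == 1) pre_log <- matrix(pre_log, nrow = 1)
    noise <- matrix(rnorm(n * length(raw), sd = config$trial_noise_sd),
                    nrow = n)
    post_log <- sweep(pre_log, 2, shift_vec, "+") + noise
    pre <- as_tibble(as.data.frame(exp(pre_log)))
    post <- as_tibble(as.data.frame(exp(post_log)))
    names(pre) <- names(post) <- raw
    pre <- derive_ratios(pre)
    post <- derive_ratios(post)
    names(pre) <- paste0("pre_", names(pre))
    names(post) <- paste0("post_", names(post))
    out <- bind_cols(
      tibble(participant_id = sprintf("%s_%02d", arm, seq_len(n)), arm = arm),
      pre, post
    )
    out
  })
}

# behavior-link signal over standardized metabolite changes
link_signal <- function(config, deltas) {
  coefs <- config$link_coefs
  z <- vapply(names(coefs), function(m) {
    d <- deltas[[m]]
    s <- sd(d)
    if (!is.finite(s) || s == 0) rep(0, length(d)) else d / s
  }, numeric(nrow(deltas)))
  if (nrow(deltas) == 1) z <- matrix(z, nrow = 1)
  signal <- drop(z %*% coefs)
  if (isTRUE(config$link_nonlinear)) {
    signal <- signal + 0.3 * (signal^2 - mean(signal^2))
  }
  signal
}

# response noise construction: when link_r2 governs, the raw noise draw is
# orthogonalized against the (centered) signal and rescaled so the link
# explains exactly link_r2 of the realized response variance, not merely in
# expectation; with a fixed vabs_noise_sd the draw is used as-is
behavior_noise <- function(config, signal, eps) {
  if (!is.null(config$vabs_noise_sd)) {
    return(eps * config$vabs_noise_sd)
  }
  s <- sd(signal)
  if (!is.finite(s) || s == 0) return(eps)
  sig_c <- signal - mean(signal)
  eps_o <- eps - sum(eps * sig_c) / sum(sig_c^2) * sig_c
  target_sd <- s * sqrt((1 - config$link_r2) / config$link_r2)
  eps_o * target_sd / sd(eps_o)
}

attach_vabs <- function(config, trial, signal, seed) {
  n <- nrow(trial)
  draws <- withr::with_seed(seed, {
    list(pre_vabs = rnorm(n, config$vabs_baseline_mean,
                          config$vabs_baseline_sd),
         eps = rnorm(n))
  })
  dvabs <- 2 + signal + behavior_noise(config, signal, draws$eps)
  trial$pre_vabs <- draws$pre_vabs
  trial$post_vabs <- draws$pre_vabs + dvabs
  trial
}

#' Generate one synthetic treatment arm
#'
#' Pre-treatment panels are drawn from the ASD distribution; post-treatment
#' panels equal the pre-treatment log-concentrations moved the arm's shift
#' fraction toward the TD log-mean, plus participant noise, with ratios
#' re-derived. The change in VABS Composite is the behavior link evaluated
#' on this arm's metabolite changes plus noise scaled to the configured
#' `link_r2` (arm-level scaling; [generate_study()] scales pooled across
#' arms instead).
#'
#' The arm's seed is derived deterministically from `config$seed` and the
#' arm's position, so arms are individually reproducible.
#'
#' @param config A [cohort_config()].
#' @param arm Arm name (one of `names(config$arms)`).
#' @param seed Optional seed override.
#' @return A trial tibble with `pre_`/`post_` panels and VABS scores.
#' @export
generate_trial <- function(config, arm, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!arm %in% names(config$arms)) {
    abort(paste0("unknown arm '", arm, "'; configured arms: ",
                 paste(names(config$arms), collapse = ", ")))
  }
  arm_index <- match(arm, names(config$arms))
  seed <- seed %||% (config$seed + 1000L * arm_index)
  trial <- gen_trial_panels(config, arm, seed)
  deltas <- delta_panels_only(trial)
  signal <- link_signal(config, deltas)
  attach_vabs(config, trial, signal, seed + 1L)
}

delta_panels_only <- function(trial) {
  out <- tibble(.rows = nrow(trial))
  for (m in focm_measures()) {
    out[[m]] <- trial[[paste0("post_", m)]] - trial[[paste0("pre_", m)]]
  }
  out
}

#' Generate a complete synthetic study
#'
#' One case-control table plus every configured treatment arm. The
#' behavior-link noise is scaled once on the pooled (all-arm) signal, so the
#' planted fraction of response variance explained across the pooled samples
#' matches `link_r2`.
#'
#' @param config A [cohort_config()].
#' @return A list with `case_control` (cohort tibble), `trials` (named list
#'   of trial tibbles), and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  case_control <- generate_case_control(config)
  panels <- lapply(names(config$arms), function(arm) {
    arm_index <- match(arm, names(config$arms))
    gen_trial_panels(config, arm, config$seed + 1000L * arm_index)
  })
  names(panels) <- names(config$arms)
  pooled_deltas <- bind_rows(lapply(panels, delta_panels_only))
  pooled_signal <- link_signal(config, pooled_deltas)
  n_pooled <- nrow(pooled_deltas)
  draws <- withr::with_seed(config$seed + 90001L, {
    list(pre_vabs = rnorm(n_pooled, config$vabs_baseline_mean,
                          config$vabs_baseline_sd),
         eps = rnorm(n_pooled))
  })
  dvabs <- 2 + pooled_signal + behavior_noise(config, pooled_signal,
                                              draws$eps)
  sizes <- vapply(panels, nrow, integer(1))
  stop_at <- cumsum(sizes)
  start_at <- stop_at - sizes + 1
  trials <- panels
  for (i in seq_along(panels)) {
    idx <- start_at[i]:stop_at[i]
    trials[[i]]$pre_vabs <- draws$pre_vabs[idx]
    trials[[i]]$post_vabs <- draws$pre_vabs[idx] + dvabs[idx]
  }
  list(case_control = case_control, trials = trials, config = config)
}
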