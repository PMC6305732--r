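# deterministic fixtures built in code

# one complete raw panel row with plausible plasma-scale values
raw_panel_row <- function(...) {
  base <- tibble::tibble(
    methionine = 25, sam = 90, sah = 20, homocysteine = 6, adenosine = 0.3,
    cysteine = 210, glu_cys = 2, cys_gly = 40, tgsh = 2.2, fgsh = 1.8,
    gssg = 0.15
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# small two-cohort table of Gaussian measurements with a configurable
# mean separation on each measure
tiny_cohort <- function(n_asd = 10, n_td = 10, m = 3, sep = 1, seed = 1,
                        measures = paste0("v", seq_len(m))) {
  withr::with_seed(seed, {
    x_asd <- matrix(stats::rnorm(n_asd * m, mean = sep), n_asd, m)
    x_td <- matrix(stats::rnorm(n_td * m, mean = 0), n_td, m)
    out <- tibble::as_tibble(as.data.frame(rbind(x_asd, x_td)))
    names(out) <- measures
    out$cohort <- rep(c("ASD", "TD"), c(n_asd, n_td))
    out
  })
}

# printed-form scatter matrices computed by explicit elementwise loops,
# independent of the package's matrix algebra
scatter_oracle <- function(x, is_asd) {
  m <- ncol(x)
  x_a <- x[is_asd, , drop = FALSE]
  x_t <- x[!is_asd, , drop = FALSE]
  n_a <- nrow(x_a)
  n_t <- nrow(x_t)
  mu <- colMeans(x)
  mu_a <- colMeans(x_a)
  mu_t <- colMeans(x_t)
  outer_pr <- function(v) outer(v, v)
  s_b <- n_a * outer_pr(mu_a - mu) + n_t * outer_pr(mu_t - mu)
  s_w <- matrix(0, m, m)
  for (i in seq_len(n_a)) s_w <- s_w + n_a * outer_pr(x_a[i, ] - mu_a)
  for (i in seq_len(n_t)) s_w <- s_w + n_t * outer_pr(x_t[i, ] - mu_t)
  list(s_b = s_b, s_w = s_w)
}

# exact Gaussian-mixture tail mass (independent of any grid)
mixture_mass_below <- function(scores, bandwidth, threshold) {
  mean(stats::pnorm(threshold, mean = scores, sd = bandwidth))
}

# small regression fixture: smooth signal plus noise
delta_fixture <- function(n = 20, p = 3, seed = 41, noise = 0.2) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    df <- tibble::as_tibble(as.data.frame(x))
    names(df) <- paste0("d", seq_len(p))
    df$dvabs <- sin(x[, 1]) + 0.5 * x[, 2] + rnorm(n, sd = noise)
    df
  })
}

# second, naive dual-form kernel PLS implementation used as an oracle:
# explicit centering matrices and per-component deflation
kpls_oracle <- function(x_train, y, x_test, width, ncomp,
                        kernel = "gaussian") {
  n <- nrow(x_train)
  kmat <- function(a, b) {
    if (kernel == "gaussian") {
      k <- matrix(0, nrow(a), nrow(b))
      for (i in seq_len(nrow(a))) {
        for (j in seq_len(nrow(b))) {
          k[i, j] <- exp(-sum((a[i, ] - b[j, ])^2) / (2 * width^2))
        }
      }
      k
    } else {
      a %*% t(b)
    }
  }
  h <- diag(n) - matrix(1, n, n) / n
  k <- kmat(x_train, x_train)
  kc <- h %*% k %*% h
  ybar <- mean(y)
  yd <- y - ybar
  kd <- kc
  t_mat <- NULL
  u_mat <- NULL
  for (a in seq_len(ncomp)) {
    u <- yd
    t_vec <- kd %*% u
    t_vec <- t_vec / sqrt(sum(t_vec^2))
    t_mat <- cbind(t_mat, t_vec)
    u_mat <- cbind(u_mat, u)
    p <- diag(n) - t_vec %*% t(t_vec)
    kd <- p %*% kd %*% p
    yd <- p %*% yd
  }
  b <- u_mat %*% solve(t(t_mat) %*% kc %*% u_mat) %*% t(t_mat) %*% (y - ybar)
  k_t <- kmat(x_test, x_train)
  ones_t <- matrix(1, nrow(x_test), n)
  k_tc <- (k_t - ones_t %*% k / n) %*% h
  drop(k_tc %*% b) + ybar
}
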