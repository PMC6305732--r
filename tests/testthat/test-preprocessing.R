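test_that("derived ratios follow their defining arithmetic", {
  p <- derive_ratios(raw_panel_row(sam = 1.5, sah = 1.5))
  expect_equal(p$sam_sah, 1)

  p <- derive_ratios(raw_panel_row(tgsh = 2, gssg = 1))
  expect_equal(p$pct_oxidized, 2 * 1 / (2 + 2 * 1))
  expect_equal(p$tgsh_gssg, 2)

  # zero numerator: fully reduced glutathione pool
  p <- derive_ratios(raw_panel_row(tgsh = 5, gssg = 0),
                     measures = "pct_oxidized")
  expect_equal(p$pct_oxidized, 0)
})

test_that("derive_ratios validates inputs and names the offending measure", {
  expect_error(derive_ratios(raw_panel_row(sah = 0), measures = "sam_sah"),
               "sah")
  expect_error(derive_ratios(raw_panel_row(gssg = 0), measures = "tgsh_gssg"),
               "gssg")
  expect_error(derive_ratios(raw_panel_row(tgsh = -1)), "tgsh")
  # pre-existing derived column inconsistent with the raw values
  bad <- raw_panel_row()
  bad$sam_sah <- 99
  expect_error(derive_ratios(bad), "sam_sah")
})

test_that("derive_ratios is idempotent and pct_oxidized is scale-invariant", {
  once <- derive_ratios(raw_panel_row())
  twice <- derive_ratios(once)
  expect_equal(twice, once)

  for (c_mult in c(0.01, 3, 1e4)) {
    scaled <- derive_ratios(raw_panel_row(tgsh = 2.2 * c_mult,
                                          gssg = 0.15 * c_mult))
    expect_equal(scaled$pct_oxidized, once$pct_oxidized, tolerance = 1e-12)
  }
})

test_that("z-score normalization has its defining train/apply behaviour", {
  df <- tibble::tibble(a = c(1, 3), b = c(0, 10), c = c(5, 6))
  params <- zscore_fit(df, c("a", "b", "c"))
  expect_equal(params$mean[params$measure == "a"], 2)
  norm <- zscore_apply(df, params)
  for (m in c("a", "b", "c")) {
    expect_lt(abs(mean(norm[[m]])), 1e-9)
    expect_lt(abs(sd(norm[[m]]) - 1), 1e-9)
  }

  # larger random table: refit after apply recovers unit moments
  big <- withr::with_seed(4, tibble::tibble(
    x = rnorm(40, 5, 2), y = runif(40), z = rexp(40)
  ))
  normed <- zscore_apply(big, zscore_fit(big, c("x", "y", "z")))
  refit <- zscore_fit(normed, c("x", "y", "z"))
  expect_true(all(abs(refit$mean) < 1e-9))
  expect_true(all(abs(refit$sd - 1) < 1e-9))

  # constant column cannot be normalized
  expect_error(zscore_fit(tibble::tibble(k = c(5, 5)), "k"), "k")
})

test_that("validation data keep their own moments under frozen parameters", {
  train <- tibble::tibble(v = c(0, 2))       # mean 1, sd sqrt(2)
  valid <- tibble::tibble(v = c(10, 12))
  params <- zscore_fit(train, "v")
  out <- zscore_apply(valid, params)
  expect_equal(mean(out$v), (11 - 1) / sd(c(0, 2)))
  expect_gt(abs(mean(out$v)), 1) # not recentred to zero

  ident <- structure(
    tibble::tibble(measure = "v", mean = 0, sd = 1),
    class = c("zscore_params", "tbl_df", "tbl", "data.frame")
  )
  expect_equal(zscore_apply(valid, ident), valid)
  expect_error(zscore_apply(tibble::tibble(w = 1), params, "w"), "w")
})

test_that("time-point averaging recomputes ratios from averaged raws", {
  a <- derive_ratios(raw_panel_row(methionine = 2, tgsh = 2, gssg = 1))
  b <- derive_ratios(raw_panel_row(methionine = 4, tgsh = 4, gssg = 1))
  avg <- average_timepoints(a, b)
  expect_equal(avg$methionine, 3)
  expect_equal(avg$pct_oxidized, 2 / (3 + 2))
  # recomputation differs from averaging the per-panel ratios
  expect_false(isTRUE(all.equal(avg$pct_oxidized,
                                mean(c(a$pct_oxidized, b$pct_oxidized)))))

  expect_equal(average_timepoints(a, a), a)
  expect_error(average_timepoints(a, a[, -1]), "measure")
})

test_that("cohort CSV loading enforces schema and completeness", {
  cc <- generate_case_control(cohort_config(n_asd = 6, n_td = 5, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cc, path)
  expect_message(loaded <- read_cohort_csv(path), regexp = NA)
  expect_equal(nrow(loaded), 11)

  # a missing value excludes that participant with a logged count
  cc2 <- cc
  cc2$methionine[2] <- NA
  readr::write_csv(cc2, path)
  expect_message(loaded2 <- read_cohort_csv(path), "1 row")
  expect_equal(nrow(loaded2), 10)

  # a missing column is a hard error naming the column
  readr::write_csv(cc[, setdiff(names(cc), "gssg")], path)
  expect_error(read_cohort_csv(path), "gssg")
})

test_that("trial CSV loading pairs pre/post panels with behavior scores", {
  tr <- generate_trial(cohort_config(seed = 5), "placebo")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tr, path)
  loaded <- read_trial_csv(path, arm = "placebo")
  expect_equal(nrow(loaded), 19)
  expect_equal(loaded$arm[1], "placebo")

  tr2 <- tr
  tr2$post_vabs[1] <- NA
  readr::write_csv(tr2, path)
  expect_message(loaded2 <- read_trial_csv(path), "1 row")
  expect_equal(nrow(loaded2), 18)

  d <- delta_table(loaded)
  expect_equal(nrow(d), 19)
  expect_equal(d$tgsh, loaded$post_tgsh - loaded$pre_tgsh)
  expect_equal(d$dvabs, loaded$post_vabs - loaded$pre_vabs)
})
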