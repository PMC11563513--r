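# Study-design statistics: preprocessing, categorization, GEE engine,
# longitudinal comparisons, thickness analyses.

test_that("preprocessing derives log-WMH and PVS percentages", {
  tab <- tibble::tibble(wmh_volume_ml = 1, icv_ml = 1000,
                        pvs_bg_vol_ml = 2, bg_roi_ml = 100,
                        pvs_cso_vol_ml = 9, cso_roi_ml = 300,
                        fazekas = 2L)
  out <- preprocess_cohort(tab)
  expect_equal(out$wmh_log, log(0.001))
  expect_equal(out$pvs_bg_pct, 2)
  expect_equal(out$pvs_cso_pct, 3)
  expect_type(out$fazekas, "double")
  bad <- tab; bad$wmh_volume_ml <- -1
  expect_error(preprocess_cohort(bad), "row")
})

test_that("OSA severity bins follow the clinical cut-offs", {
  x <- c(20, 31, 30, 15, 5, 14.9, 100)
  expect_warning(sv <- categorize_severity(c(x, 2)), "subthreshold")
  expect_equal(as.character(sv),
               c("moderate", "severe", "moderate", "moderate", "mild",
                 "mild", "severe", "subthreshold"))
})

test_that("both adherence definitions behave at their boundaries", {
  out <- categorize_adherence(mean_usage_hr = c(6.7, 4.0, 3.99, NA),
                              pct_nights_ge4 = c(85, 79, 80, 10))
  expect_equal(out$adherence_mean,
               c("optimal", "optimal", "sub_optimal", NA))
  expect_equal(out$adherence_nightly,
               c("optimal", "sub_optimal", "optimal", "sub_optimal"))
  nightly <- categorize_adherence(nightly = list(rep(5, 10),
                                                 c(rep(5, 7), rep(1, 3)),
                                                 numeric(0)))
  expect_equal(nightly$adherence_nightly, c("optimal", "sub_optimal", NA))
})

test_that("GEE with independence equals OLS on independent clusters", {
  set.seed(1)
  n <- 150
  X <- cbind(`(Intercept)` = 1, x = rnorm(n), b = rbinom(n, 1, 0.4))
  y <- 0.5 * X[, 2] - 0.3 * X[, 3] + rnorm(n)
  fit <- gee_gaussian(y, X, id = seq_len(n), corstr = "independence")
  ols <- lm(y ~ X[, 2] + X[, 3])
  expect_lt(max(abs(fit$coefficients - coef(ols))), 1e-6)
})

test_that("exchangeable GEE matches a dense GLS solve at the same alpha", {
  set.seed(2)
  n <- 120
  id <- rep(1:60, each = 2)
  b <- rnorm(60)[id]
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  y <- 0.4 * X[, 2] + b + rnorm(n, 0, 0.7)
  fit <- gee_gaussian(y, X, id, corstr = "exchangeable")
  expect_true(fit$converged)
  R <- diag(n)
  for (cl in split(1:n, id)) {
    R[cl[1], cl[2]] <- fit$alpha; R[cl[2], cl[1]] <- fit$alpha
  }
  beta_gls <- solve(t(X) %*% solve(R, X), t(X) %*% solve(R, y))
  expect_lt(max(abs(fit$coefficients - beta_gls)), 1e-10)
  expect_gt(fit$alpha, 0.2)   # the shared intercept induces correlation
})

test_that("GEE agrees with Python statsmodels on a two-eye fixture", {
  set.seed(3)
  n <- 120
  id <- rep(1:60, each = 2)
  X <- cbind(`(Intercept)` = 1, x = rnorm(n), b = rbinom(n, 1, 0.3))
  y <- 0.5 * X[, 2] - 0.3 * X[, 3] + rnorm(60)[id] * 0.6 + rnorm(n)
  fit <- gee_gaussian(y, X, id, corstr = "exchangeable")
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(y = y, x = X[, 2], b = X[, 3], id = id), csv,
            row.names = FALSE)
  script <- paste(
    "import pandas as pd, statsmodels.api as sm,",
    "statsmodels.formula.api as smf;",
    sprintf("d = pd.read_csv('%s');", csv),
    "m = smf.gee('y ~ x + b', groups='id', data=d,",
    "cov_struct=sm.cov_struct.Exchangeable(),",
    "family=sm.families.Gaussian()).fit();",
    "print(*m.params.values, *m.bse.values)")
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  ref <- as.numeric(strsplit(tail(out, 1), " +")[[1]])
  expect_lt(max(abs(fit$coefficients - ref[1:3])), 1e-6)
  expect_lt(max(abs(fit$robust_se - ref[4:6])), 1e-6)
})

test_that("standardized betas are invariant to predictor rescaling", {
  tab <- test_cohort(n = 120, seed = 4,
                     effects = list(fazekas = c(radius_large_um = 0.3)))
  tab <- preprocess_cohort(tab)
  f1 <- fit_gee_crosssectional(tab, "fazekas", "radius_large_um",
                               covariates = c("age", "sex_female"))
  tab2 <- tab
  tab2$radius_large_um <- tab2$radius_large_um * 1000
  tab2$age <- tab2$age / 365.25
  f2 <- fit_gee_crosssectional(tab2, "fazekas", "radius_large_um",
                               covariates = c("age", "sex_female"))
  expect_lt(abs(f1$standardized_beta - f2$standardized_beta), 1e-8)
  expect_lt(abs(f1$p_value - f2$p_value), 1e-8)
})

test_that("exclusion bookkeeping: rows in = rows used + rows excluded", {
  tab <- preprocess_cohort(test_cohort(n = 50, seed = 6))
  tab$sbp[which(tab$visit == "baseline")[c(3, 10, 11)]] <- NA
  fit <- fit_gee_crosssectional(tab, "fazekas", "foveal_vd")
  n_base <- sum(tab$visit == "baseline")
  expect_equal(fit$n_eyes + fit$n_excluded, n_base)
  expect_equal(fit$n_excluded, 3)
})

test_that("cross-sectional GEE errors with too few participants", {
  tab <- preprocess_cohort(test_cohort(n = 8, seed = 7))
  expect_error(fit_gee_crosssectional(tab, "fazekas", "foveal_vd"),
               "fewer than 10")
})

test_that("one eye per participant reduces GEE to standardized OLS", {
  tab <- preprocess_cohort(generate_cohort(cohort_sim_params(
    n_participants = 80, eyes_per_participant = 1, seed = 8))$table)
  fit <- fit_gee_crosssectional(tab, "fazekas", "foveal_vd",
                                covariates = c("age", "bmi"))
  base <- tab[tab$visit == "baseline", ]
  d <- data.frame(y = scale(base$fazekas)[, 1],
                  p = scale(base$foveal_vd)[, 1],
                  a = scale(base$age)[, 1], b = scale(base$bmi)[, 1])
  ols <- lm(y ~ p + a + b, d)
  expect_lt(abs(fit$standardized_beta - coef(ols)[["p"]]), 1e-6)
})

test_that("longitudinal comparison: identical groups and degenerate data", {
  tab <- test_cohort(n = 60, seed = 9, miss = 0)
  res <- longitudinal_group_comparison(tab, "faz_area_mm2", "od")
  expect_true(res$test_used %in% c("t", "mann_whitney"))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  # identical change values in both groups -> missing (degenerate variance)
  tab2 <- tab
  tab2$faz_area_mm2 <- 0.3                   # constant at both visits
  res2 <- longitudinal_group_comparison(tab2, "faz_area_mm2", "od")
  expect_true(is.na(res2$p_value))
  # too few in a group -> missing, not an error
  tab3 <- tab[tab$participant_id %in% unique(tab$participant_id)[1:4], ]
  res3 <- longitudinal_group_comparison(tab3, "faz_area_mm2", "od")
  expect_true(is.na(res3$p_value))
})

test_that("a large group shift is detected with high power", {
  hits <- 0
  for (i in 1:60) {
    set.seed(400 + i)
    g1 <- rnorm(20, 0, 1); g2 <- rnorm(20, 2, 1)
    p <- if (shapiro.test(g1)$p.value > 0.05 &&
               shapiro.test(g2)$p.value > 0.05)
      t.test(g1, g2)$p.value
    else suppressWarnings(wilcox.test(g1, g2, exact = FALSE)$p.value)
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits / 60, 0.95)
})

test_that("change-on-usage GEE recovers a configured effect", {
  est <- vapply(1:30, function(i) {
    tab <- test_cohort(n = 300, seed = 500 + i,
                       change = c(faz_area_mm2 = 0.3), miss = 0.1)
    fit_gee_change_on_usage(tab, "faz_area_mm2",
                            covariates = c("age", "sex_female"))$standardized_beta
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.3), 0.05)
})

test_that("change-on-usage GEE rejects degenerate inputs", {
  tab <- test_cohort(n = 40, seed = 11)
  tab$cpap_usage_hr_per_night <- 5            # zero variance
  expect_error(fit_gee_change_on_usage(tab, "faz_area_mm2"),
               "zero variance")
  tab2 <- test_cohort(n = 40, seed = 11)
  tab2 <- tab2[tab2$visit == "baseline", ]    # no follow-up
  expect_error(fit_gee_change_on_usage(tab2, "faz_area_mm2"),
               "both visits")
})

test_that("thickness comparisons produce the Table-3-style cell grid", {
  tab <- test_cohort(n = 60, seed = 12, miss = 0.1)
  res <- thickness_comparisons(tab)
  expect_setequal(unique(res$analysis),
                  c("baseline_moderate_vs_severe", "paired_pre_post"))
  expect_equal(sum(res$analysis == "baseline_moderate_vs_severe"), 6)
  expect_equal(sum(res$analysis == "paired_pre_post"), 24)
  ok <- !is.na(res$p_value)
  expect_true(all(res$p_value[ok] >= 0 & res$p_value[ok] <= 1))
  # identical pre/post yields missing paired cells, never an error
  tab2 <- tab
  for (rg in c("macular_foveal_um", "macular_volume_mm3"))
    tab2[[rg]] <- 300
  res2 <- thickness_comparisons(tab2)
  cells <- res2[res2$analysis == "paired_pre_post" &
                  res2$region == "macular_foveal_um", ]
  expect_true(all(is.na(cells$p_value)))
})

test_that("the full association suite runs end-to-end at study scale", {
  tab <- test_cohort(n = 43, seed = 13,
                     effects = list(pvs_bg_count = c(foveal_vd = 0.4)))
  suite <- run_association_suite(
    tab, phenotypes = c("foveal_vd", "faz_area_mm2", "radius_large_um"),
    svd_outcomes = c("wmh_log", "fazekas", "pvs_bg_count"),
    sleep_vars = c("pahi", "spo2_nadir"))
  expect_equal(nrow(suite$baseline_svd), 9)
  expect_equal(nrow(suite$baseline_sleep), 6)
  expect_true(all(c("standardized_beta", "ci_low", "ci_high", "p_value")
                  %in% names(suite$baseline_svd)))
  expect_true(all(suite$baseline_svd$ci_low <=
                    suite$baseline_svd$standardized_beta))
  expect_true(all(suite$baseline_svd$standardized_beta <=
                    suite$baseline_svd$ci_high))
  expect_equal(nrow(suite$longitudinal), 6)
  expect_equal(nrow(suite$change_on_usage), 3)
  expect_gt(nrow(suite$thickness), 0)
})
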