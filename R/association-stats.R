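# The study-design statistics: preprocessing of SVD outcome columns,
# OSA severity and CPAP adherence categorization, cross-sectional GEE
# with both eyes clustered by participant, per-eye longitudinal group
# comparisons, GEE of phenotype change on CPAP usage, and macular
# thickness comparisons. P-values are reported unadjusted throughout
# (the analyses are exploratory; no multiplicity correction).

#' Preprocess a cohort table for association analyses
#'
#' White-matter-hyperintensity volume is normalized for intracranial
#' volume and log-transformed (`wmh_log = log(wmh_volume_ml / icv_ml)`,
#' given its highly skewed distribution); perivascular-space volumes are
#' expressed as a percentage of the corresponding region-of-interest
#' volume (`pvs_bg_pct`, `pvs_cso_pct`); ordinal brain scores (Fazekas,
#' atrophy) are carried as numeric, used as continuous to avoid
#' overfitting sparse upper categories. Rows with missing values are not
#' dropped here: each analysis excludes its own incomplete rows and
#' reports the exclusion count.
#'
#' @param table a cohort tibble (see [generate_cohort()]).
#' @return The table with derived columns added.
#' @export
preprocess_cohort <- function(table) {
  tab <- table
  if (all(c("wmh_volume_ml", "icv_ml") %in% names(tab))) {
    bad <- which(!is.na(tab$wmh_volume_ml) & !is.na(tab$icv_ml) &
                   (tab$wmh_volume_ml <= 0 | tab$icv_ml <= 0))
    if (length(bad))
      stop("nonpositive WMH or ICV volume in row(s): ",
           paste(head(bad, 5), collapse = ", "))
    tab$wmh_log <- log(tab$wmh_volume_ml / tab$icv_ml)
  }
  if (all(c("pvs_bg_vol_ml", "bg_roi_ml") %in% names(tab)))
    tab$pvs_bg_pct <- 100 * tab$pvs_bg_vol_ml / tab$bg_roi_ml
  if (all(c("pvs_cso_vol_ml", "cso_roi_ml") %in% names(tab)))
    tab$pvs_cso_pct <- 100 * tab$pvs_cso_vol_ml / tab$cso_roi_ml
  for (v in c("fazekas", "superficial_atrophy", "deep_atrophy"))
    if (v %in% names(tab)) tab[[v]] <- as.numeric(tab[[v]])
  tab
}

#' Categorize OSA severity from the pAHI
#'
#' Standard clinical bins: mild 5-14, moderate 15-30 (closed upper
#' bound), severe above 30 events/hour. Values below 5 are labeled
#' `"subthreshold"` and flagged with a warning, since they fall below
#' the mild range.
#'
#' @param pahi numeric vector of apnea-hypopnea indices (events/hr, >= 0).
#' @return Factor with levels subthreshold, mild, moderate, severe.
#' @export
categorize_severity <- function(pahi) {
  stopifnot(all(pahi >= 0, na.rm = TRUE))
  out <- cut(pahi, breaks = c(-Inf, 5, 15, 30, Inf),
             labels = c("subthreshold", "mild", "moderate", "severe"),
             right = FALSE)
  # the moderate bin is stated with a closed upper bound: 30 is moderate
  out[!is.na(pahi) & pahi == 30] <- "moderate"
  if (any(out == "subthreshold", na.rm = TRUE))
    warning(sum(out == "subthreshold", na.rm = TRUE),
            " pAHI value(s) below 5 events/hr labeled 'subthreshold'")
  out
}

#' Categorize CPAP adherence (two definitions)
#'
#' Definition A (nightly): optimal if usage reached at least 4 hr/night
#' on at least 80% of nights. Definition B (mean): optimal if mean usage
#' is at least 4 hr/night (boundary inclusive). Both are returned;
#' analyses select one per configuration. Missing inputs yield `NA`.
#'
#' @param mean_usage_hr mean nightly usage, hours.
#' @param pct_nights_ge4 percentage of nights with >= 4 hr of use.
#' @param nightly optional list of per-night usage vectors; when given,
#'   both summaries are computed from it and the other arguments are
#'   ignored.
#' @return Tibble with columns `adherence_nightly` (definition A) and
#'   `adherence_mean` (definition B), values `"optimal"`/`"sub_optimal"`.
#' @export
categorize_adherence <- function(mean_usage_hr = NULL, pct_nights_ge4 = NULL,
                                 nightly = NULL) {
  if (!is.null(nightly)) {
    mean_usage_hr <- vapply(nightly, function(u)
      if (length(u) == 0) NA_real_ else mean(u), numeric(1))
    pct_nights_ge4 <- vapply(nightly, function(u)
      if (length(u) == 0) NA_real_ else 100 * mean(u >= 4), numeric(1))
  }
  n <- max(length(mean_usage_hr), length(pct_nights_ge4))
  if (is.null(mean_usage_hr)) mean_usage_hr <- rep(NA_real_, n)
  if (is.null(pct_nights_ge4)) pct_nights_ge4 <- rep(NA_real_, n)
  lab <- function(ok) ifelse(is.na(ok), NA_character_,
                             ifelse(ok, "optimal", "sub_optimal"))
  tibble::tibble(
    adherence_nightly = lab(pct_nights_ge4 >= 80),
    adherence_mean = lab(mean_usage_hr >= 4))
}

#' Cross-sectional GEE of an outcome on a retinal phenotype
#'
#' Both eyes enter one analysis, clustered by participant, with an
#' exchangeable working correlation and robust standard errors. The
#' outcome and all continuous predictors are z-scored on the analysis
#' sample so the reported coefficient is standardized; binary covariates
#' stay 0/1 so group contrasts remain interpretable. Rows with missing
#' values in any model variable are excluded and counted.
#'
#' @param table cohort tibble (typically after [preprocess_cohort()]).
#' @param outcome,phenotype column names.
#' @param covariates character vector of adjustment columns (default:
#'   the study's covariate set).
#' @param visit which visit's rows to use.
#' @param corstr working correlation passed to [gee_gaussian()].
#' @return A one-row `gee_result` tibble: `outcome`, `phenotype`,
#'   `standardized_beta`, `ci_low`, `ci_high`, `p_value`, `n_eyes`,
#'   `n_participants`, `n_excluded`, `alpha`.
#' @export
fit_gee_crosssectional <- function(table, outcome, phenotype,
                                   covariates = c("age", "sex_female", "sbp",
                                                  "bmi", "diabetes",
                                                  "hypercholesterolemia",
                                                  "smoking", "image_quality"),
                                   visit = "baseline",
                                   corstr = "exchangeable") {
  dat <- table[table$visit == visit, , drop = FALSE]
  vars <- c(outcome, phenotype, covariates)
  stopifnot(all(vars %in% names(dat)))
  cc <- complete.cases(dat[, vars])
  n_excluded <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]
  n_clusters <- length(unique(dat$participant_id))
  if (n_clusters < 10)
    stop("fewer than 10 participants after exclusions (", n_clusters, ")")
  des <- standardized_design(dat, outcome, c(phenotype, covariates))
  fit <- gee_gaussian(des$y, des$X, dat$participant_id, corstr = corstr)
  if (!fit$converged) stop("GEE did not converge for ", outcome, " ~ ",
                           phenotype, " (alpha = ", round(fit$alpha, 3), ")")
  beta <- fit$coefficients[[phenotype]]
  se <- fit$robust_se[[phenotype]]
  z <- beta / se
  tibble::tibble(outcome = outcome, phenotype = phenotype,
                 standardized_beta = beta,
                 ci_low = beta - qnorm(0.975) * se,
                 ci_high = beta + qnorm(0.975) * se,
                 p_value = 2 * pnorm(-abs(z)),
                 n_eyes = fit$n_obs, n_participants = fit$n_clusters,
                 n_excluded = n_excluded, alpha = fit$alpha)
}

# per-participant-eye change (followup - baseline) for one column,
# joined with baseline covariates
change_table <- function(table, phenotype) {
  base <- table[table$visit == "baseline", , drop = FALSE]
  fu <- table[table$visit == "followup", , drop = FALSE]
  key_b <- paste(base$participant_id, base$eye)
  key_f <- paste(fu$participant_id, fu$eye)
  idx <- match(key_f, key_b)
  ok <- !is.na(idx)
  out <- base[idx[ok], , drop = FALSE]
  out$change <- fu[[phenotype]][ok] - base[[phenotype]][idx[ok]]
  out
}

#' Longitudinal adherence-group comparison for one phenotype and eye
#'
#' Per-eye change (follow-up minus baseline) compared between optimal
#' and sub-optimal CPAP adherence (mean-usage definition) with a
#' two-tailed t-test when both groups pass a Shapiro-Wilk normality
#' check at alpha = 0.05, otherwise a Mann-Whitney U test; the test used
#' is reported. Groups with fewer than 3 observations yield a missing
#' result rather than an error.
#'
#' @param table cohort tibble with both visits.
#' @param phenotype column name.
#' @param eye `"od"` or `"os"`.
#' @return One-row tibble: `phenotype`, `eye`, `test_used`, `statistic`,
#'   `p_value`, `n_optimal`, `n_suboptimal`, `mean_change_optimal`,
#'   `mean_change_suboptimal`.
#' @export
longitudinal_group_comparison <- function(table, phenotype, eye) {
  ch <- change_table(table[table$eye == eye, , drop = FALSE], phenotype)
  adh <- categorize_adherence(mean_usage_hr = ch$cpap_usage_hr_per_night)$adherence_mean
  g1 <- ch$change[adh == "optimal" & !is.na(adh) & !is.na(ch$change)]
  g2 <- ch$change[adh == "sub_optimal" & !is.na(adh) & !is.na(ch$change)]
  miss <- tibble::tibble(phenotype = phenotype, eye = eye,
                         test_used = NA_character_, statistic = NA_real_,
                         p_value = NA_real_, n_optimal = length(g1),
                         n_suboptimal = length(g2),
                         mean_change_optimal = NA_real_,
                         mean_change_suboptimal = NA_real_)
  if (length(g1) < 3 || length(g2) < 3) return(miss)
  if (sd(g1) == 0 && sd(g2) == 0) return(miss)  # degenerate variance
  normal_ok <- function(g) {
    if (sd(g) == 0) return(FALSE)
    shapiro.test(g)$p.value > 0.05
  }
  if (normal_ok(g1) && normal_ok(g2)) {
    tst <- t.test(g1, g2)
    used <- "t"
  } else {
    tst <- suppressWarnings(wilcox.test(g1, g2, exact = FALSE))
    used <- "mann_whitney"
  }
  tibble::tibble(phenotype = phenotype, eye = eye, test_used = used,
                 statistic = unname(tst$statistic),
                 p_value = tst$p.value,
                 n_optimal = length(g1), n_suboptimal = length(g2),
                 mean_change_optimal = mean(g1),
                 mean_change_suboptimal = mean(g2))
}

#' GEE of phenotype change on CPAP usage
#'
#' The amount of change in a retinal phenotype (follow-up minus
#' baseline) is the dependent variable and mean CPAP usage (hours per
#' night) the independent variable, adjusted for covariates, with both
#' eyes clustered by participant; standardization as in
#' [fit_gee_crosssectional()].
#'
#' @param table cohort tibble with both visits.
#' @param phenotype column name.
#' @param covariates adjustment columns.
#' @param corstr working correlation.
#' @return A one-row `gee_result` tibble (outcome = `"change"`).
#' @export
fit_gee_change_on_usage <- function(table, phenotype,
                                    covariates = c("age", "sex_female", "sbp",
                                                   "bmi", "diabetes",
                                                   "hypercholesterolemia",
                                                   "smoking"),
                                    corstr = "exchangeable") {
  ch <- change_table(table, phenotype)
  if (nrow(ch) == 0) stop("no participants with both visits")
  vars <- c("change", "cpap_usage_hr_per_night", covariates)
  cc <- complete.cases(ch[, vars])
  ch <- ch[cc, , drop = FALSE]
  if (sd(ch$cpap_usage_hr_per_night) == 0)
    stop("CPAP usage has zero variance")
  des <- standardized_design(ch, "change",
                             c("cpap_usage_hr_per_night", covariates))
  fit <- gee_gaussian(des$y, des$X, ch$participant_id, corstr = corstr)
  beta <- fit$coefficients[["cpap_usage_hr_per_night"]]
  se <- fit$robust_se[["cpap_usage_hr_per_night"]]
  tibble::tibble(outcome = paste0("change_", phenotype),
                 phenotype = "cpap_usage_hr_per_night",
                 standardized_beta = beta,
                 ci_low = beta - qnorm(0.975) * se,
                 ci_high = beta + qnorm(0.975) * se,
                 p_value = 2 * pnorm(-abs(beta / se)),
                 n_eyes = fit$n_obs, n_participants = fit$n_clusters,
                 n_excluded = sum(!cc), alpha = fit$alpha)
}

#' Macular thickness comparisons
#'
#' Two analyses on the device-reported thickness columns: (1) baseline
#' moderate-vs-severe OSA comparison per region (t-test when both groups
#' pass the Shapiro-Wilk gate, Mann-Whitney otherwise); (2) within-group
#' pre/post paired t-tests per region, split by OSA severity and CPAP
#' adherence class (mean-usage definition). Cells with fewer than 3
#' participants, or with zero-variance paired differences, are reported
#' as missing.
#'
#' @param table cohort tibble with both visits and thickness columns.
#' @param regions thickness column names.
#' @return Tibble with one row per analysis cell: `analysis`, `region`,
#'   `group`, `test_used`, `statistic`, `p_value`, `n`.
#' @export
thickness_comparisons <- function(table,
                                  regions = c("macular_foveal_um",
                                              "macular_superior_um",
                                              "macular_nasal_um",
                                              "macular_inferior_um",
                                              "macular_temporal_um",
                                              "macular_volume_mm3")) {
  stopifnot(all(regions %in% names(table)))
  tab <- table
  tab$severity <- categorize_severity(tab$pahi)
  out <- list()
  add <- function(...) out[[length(out) + 1L]] <<- tibble::tibble(...)

  base <- tab[tab$visit == "baseline", , drop = FALSE]
  for (rg in regions) {
    g_mod <- base[[rg]][base$severity == "moderate" & !is.na(base[[rg]])]
    g_sev <- base[[rg]][base$severity == "severe" & !is.na(base[[rg]])]
    if (length(g_mod) < 3 || length(g_sev) < 3) {
      add(analysis = "baseline_moderate_vs_severe", region = rg,
          group = "all", test_used = NA_character_, statistic = NA_real_,
          p_value = NA_real_, n = length(g_mod) + length(g_sev))
      next
    }
    normal_ok <- function(g) sd(g) > 0 && shapiro.test(g)$p.value > 0.05
    if (normal_ok(g_mod) && normal_ok(g_sev)) {
      tst <- t.test(g_mod, g_sev); used <- "t"
    } else {
      tst <- suppressWarnings(wilcox.test(g_mod, g_sev, exact = FALSE))
      used <- "mann_whitney"
    }
    add(analysis = "baseline_moderate_vs_severe", region = rg, group = "all",
        test_used = used, statistic = unname(tst$statistic),
        p_value = tst$p.value, n = length(g_mod) + length(g_sev))
  }

  adh <- categorize_adherence(
    mean_usage_hr = tab$cpap_usage_hr_per_night)$adherence_mean
  tab$adherence <- adh
  for (sev in c("moderate", "severe")) {
    for (cls in c("optimal", "sub_optimal")) {
      sub <- tab[tab$severity == sev & tab$adherence == cls &
                   !is.na(tab$adherence), , drop = FALSE]
      for (rg in regions) {
        ch <- change_table(sub, rg)
        d <- ch$change[!is.na(ch$change)]
        grp <- paste(sev, cls, sep = "/")
        if (length(d) < 3 || sd(d) == 0) {
          add(analysis = "paired_pre_post", region = rg, group = grp,
              test_used = NA_character_, statistic = NA_real_,
              p_value = NA_real_, n = length(d))
        } else {
          tst <- t.test(d)
          add(analysis = "paired_pre_post", region = rg, group = grp,
              test_used = "paired_t", statistic = unname(tst$statistic),
              p_value = tst$p.value, n = length(d))
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Run the full association suite on a cohort
#'
#' End-to-end reproduction of the study design on one table: baseline
#' GEE of every phenotype against every SVD outcome and sleep variable
#' (forest-plot-ready, standardized betas with 95% CI), per-eye
#' longitudinal adherence comparisons, GEE of phenotype change on CPAP
#' usage, and the thickness comparisons. Individual model failures (for
#' example too few complete rows) are caught and logged, not fatal.
#'
#' @param table cohort tibble (raw; preprocessing is applied here).
#' @param phenotypes,svd_outcomes,sleep_vars column sets to cross.
#' @param covariates adjustment set for the GEE models.
#' @return List of tibbles: `baseline_svd`, `baseline_sleep`,
#'   `longitudinal`, `change_on_usage`, `thickness`, and a character
#'   vector `log` of skipped models.
#' @export
run_association_suite <- function(table,
                                  phenotypes = c("parafoveal_vd", "foveal_vd",
                                                 "branching_points",
                                                 "faz_area_mm2",
                                                 "tortuosity_large",
                                                 "tortuosity_small",
                                                 "radius_large_um",
                                                 "radius_small_um",
                                                 "ks_score", "symmetry_ratio",
                                                 "bifurcation_distance_large_um",
                                                 "bifurcation_distance_small_um",
                                                 "prnfl_thickness_um"),
                                  svd_outcomes = c("wmh_log", "fazekas",
                                                   "superficial_atrophy",
                                                   "deep_atrophy",
                                                   "pvs_bg_pct", "pvs_cso_pct",
                                                   "pvs_bg_count",
                                                   "pvs_cso_count"),
                                  sleep_vars = c("pahi", "spo2_mean",
                                                 "spo2_nadir"),
                                  covariates = c("age", "sex_female", "sbp",
                                                 "bmi", "diabetes",
                                                 "hypercholesterolemia",
                                                 "smoking", "image_quality")) {
  tab <- preprocess_cohort(table)
  log <- character()
  fit_all <- function(outcomes) {
    res <- list()
    for (o in outcomes) for (p in phenotypes) {
      r <- tryCatch(fit_gee_crosssectional(tab, o, p, covariates),
                    error = function(e) {
                      log <<- c(log, paste0(o, " ~ ", p, ": ",
                                            conditionMessage(e)))
                      NULL
                    })
      if (!is.null(r)) res[[length(res) + 1L]] <- r
    }
    if (length(res)) do.call(rbind, res) else NULL
  }
  baseline_svd <- fit_all(svd_outcomes)
  baseline_sleep <- fit_all(sleep_vars)

  longi <- list()
  for (e in intersect(c("od", "os"), unique(tab$eye)))
    for (p in phenotypes)
      longi[[length(longi) + 1L]] <- longitudinal_group_comparison(tab, p, e)
  longitudinal <- do.call(rbind, longi)

  chg <- list()
  for (p in phenotypes) {
    r <- tryCatch(fit_gee_change_on_usage(tab, p,
                                          covariates = setdiff(covariates,
                                                               "image_quality")),
                  error = function(e) {
                    log <<- c(log, paste0("change ", p, ": ",
                                          conditionMessage(e)))
                    NULL
                  })
    if (!is.null(r)) chg[[length(chg) + 1L]] <- r
  }
  change_on_usage <- if (length(chg)) do.call(rbind, chg) else NULL

  thickness <- tryCatch(thickness_comparisons(tab), error = function(e) {
    log <<- c(log, paste0("thickness: ", conditionMessage(e)))
    NULL
  })
  list(baseline_svd = baseline_svd, baseline_sleep = baseline_sleep,
       longitudinal = longitudinal, change_on_usage = change_on_usage,
       thickness = thickness, log = log)
}
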