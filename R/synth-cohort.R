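# Simulates two-eye cohort tables with known standardized effect sizes
# and within-participant correlation, emulating an OSA/CPAP study design:
# both eyes per participant, baseline and follow-up visits, covariates,
# sleep variables, SVD outcome markers and CPAP usage.

#' Cohort simulation parameters
#'
#' The generator draws, per participant, covariates mimicking the target
#' study population (middle-aged, high BMI, moderate-to-severe OSA), one
#' row per eye per visit. Eye-level phenotypes and outcomes share a
#' participant-level random component so that fellow eyes are correlated:
#' for a variable with unit variance, the participant component has
#' variance `within_participant_corr`, which is the intraclass
#' correlation between fellow eyes under null effects.
#'
#' Outcomes listed in `effect_sizes` are built as
#' \eqn{y = \sum_j \beta_j z_j + b + \epsilon} on the z-scale, where
#' \eqn{z_j} are standardized predictors (phenotypes or covariates),
#' \eqn{b} is the participant intercept and the residual variance is
#' scaled so \eqn{Var(y) = 1}; each \eqn{\beta_j} is therefore the true
#' standardized coefficient. `sum(beta^2)` must stay below 1.
#'
#' @param n_participants number of participants.
#' @param eyes_per_participant 1 or 2.
#' @param effect_sizes named list: outcome name -> named numeric vector
#'   of standardized betas on predictor columns, e.g.
#'   `list(wmh_log = c(radius_large_um = 0.4))`. Empty list = all-null.
#' @param change_effects named numeric vector of standardized effects of
#'   nightly CPAP usage on phenotype change (follow-up minus baseline),
#'   e.g. `c(faz_area_mm2 = 0.3)`.
#' @param within_participant_corr ICC rho in \[0, 1) between fellow eyes.
#' @param missing_followup_fraction probability that a participant's eye
#'   lacks the follow-up visit; scalar, or named `c(od = ..., os = ...)`.
#' @param seed integer seed (all draws flow through it).
#' @return A `cohort_sim_params` list.
#' @export
cohort_sim_params <- function(n_participants = 43L,
                              eyes_per_participant = 2L,
                              effect_sizes = list(),
                              change_effects = c(),
                              within_participant_corr = 0.5,
                              missing_followup_fraction = c(od = 0.14,
                                                            os = 0.28),
                              seed = 1L) {
  stopifnot(n_participants >= 1, eyes_per_participant %in% 1:2,
            within_participant_corr >= 0, within_participant_corr < 1,
            all(unlist(missing_followup_fraction) >= 0),
            all(unlist(missing_followup_fraction) < 1))
  for (b in effect_sizes) {
    stopifnot(all(is.finite(b)))
    if (sum(b^2) >= 1)
      stop("sum of squared effect sizes must be < 1 for a unit-variance outcome")
  }
  if (length(missing_followup_fraction) == 1)
    missing_followup_fraction <- c(od = unname(missing_followup_fraction),
                                   os = unname(missing_followup_fraction))
  structure(list(n_participants = as.integer(n_participants),
                 eyes_per_participant = as.integer(eyes_per_participant),
                 effect_sizes = effect_sizes,
                 change_effects = change_effects,
                 within_participant_corr = within_participant_corr,
                 missing_followup_fraction = missing_followup_fraction,
                 seed = as.integer(seed)),
            class = "cohort_sim_params")
}

# natural-scale location/spread used to dress z-scores; means/SDs chosen
# to resemble the study population and plausible 3x3 mm SVC panels
cohort_phenotype_scales <- function() {
  list(parafoveal_vd = c(0.34, 0.03), foveal_vd = c(0.18, 0.04),
       branching_points = c(110, 20), faz_area_mm2 = c(0.30, 0.09),
       tortuosity_large = c(1.10, 0.03), tortuosity_small = c(1.14, 0.04),
       radius_large_um = c(14.5, 1.5), radius_small_um = c(6.1, 0.8),
       ks_score = c(0.22, 0.07), symmetry_ratio = c(0.78, 0.06),
       bifurcation_distance_large_um = c(180, 35),
       bifurcation_distance_small_um = c(95, 20),
       prnfl_thickness_um = c(98, 9),
       macular_foveal_um = c(284, 24), macular_superior_um = c(348, 17),
       macular_nasal_um = c(350, 17), macular_inferior_um = c(345, 19),
       macular_temporal_um = c(335, 17), macular_volume_mm3 = c(8.7, 0.4))
}

#' Simulate a two-eye cohort table
#'
#' Long-format table, one row per participant-eye-visit, with retinal
#' phenotypes (including device pass-through thickness columns),
#' covariates, sleep variables, SVD outcome markers, and CPAP usage.
#' Deterministic for a fixed seed. Columns `<name>_z` hold the z-scale
#' versions of generated outcomes used by the effect machinery; outcomes
#' are also emitted on a natural scale.
#'
#' @param params a [cohort_sim_params()].
#' @return List with `table` (tibble) and `true_effects` (the effect
#'   specification echoed back).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  withr::with_seed(params$seed, generate_cohort_impl(params))
}

generate_cohort_impl <- function(params) {
  n <- params$n_participants
  eyes <- c("od", "os")[seq_len(params$eyes_per_participant)]
  rho <- params$within_participant_corr

  # participant-level covariates (arbitrary documented distributions
  # resembling the study's Table 1 population)
  smoking_lv <- c("never", "ex", "current")
  ppl <- tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    age = rnorm(n, 50.1, 9.1),
    sex_female = rbinom(n, 1, 0.33),
    sbp = rnorm(n, 132, 14),
    bmi = rnorm(n, 34.8, 6.1),
    diabetes = rbinom(n, 1, 0.09),
    hypercholesterolemia = rbinom(n, 1, 0.28),
    smoking = factor(sample(smoking_lv, n, replace = TRUE,
                            prob = c(0.49, 0.33, 0.18)), levels = smoking_lv),
    pahi = pmax(5.5, rnorm(n, 53.7, 24.7)),
    spo2_mean = rnorm(n, 92.9, 2.0),
    spo2_nadir = rnorm(n, 75.7, 9.3),
    icv_ml = rnorm(n, 1476, 161),
    bg_roi_ml = rnorm(n, 50, 5),
    cso_roi_ml = rnorm(n, 260, 25),
    # usage mixture keeps both adherence classes populated
    cpap_usage_hr_per_night = pmin(10, pmax(0, ifelse(
      runif(n) < 0.45, rnorm(n, 6.7, 0.9), rnorm(n, 3.0, 1.8)))))
  ppl$pct_nights_over_4hr <- pmin(100, pmax(0,
    15 + 11 * ppl$cpap_usage_hr_per_night + rnorm(n, 0, 8)))

  phen_names <- names(cohort_phenotype_scales())
  scales <- cohort_phenotype_scales()

  # eye-level phenotype z-scores with participant-shared component
  z_eye <- function() {
    a <- rnorm(n)
    out <- lapply(eyes, function(e) sqrt(rho) * a + sqrt(1 - rho) * rnorm(n))
    names(out) <- eyes
    out
  }
  phen_z <- lapply(phen_names, function(p) z_eye())
  names(phen_z) <- phen_names

  rows <- list()
  for (e in eyes) {
    tab <- ppl
    tab$eye <- e
    tab$image_quality <- rnorm(n, 30, 4)
    for (p in phen_names) {
      z <- phen_z[[p]][[e]]
      tab[[paste0(p, "_z")]] <- z
      tab[[p]] <- scales[[p]][1] + scales[[p]][2] * z
    }
    rows[[e]] <- tab
  }
  base <- do.call(rbind, rows)
  base$visit <- "baseline"

  # outcomes: y = sum beta_j z_j + b + eps on the z-scale, Var(y) = 1
  outcome_scales <- list(
    fazekas = c(2, 1.1), wmh_volume_ml = NA, superficial_atrophy = c(1.3, 0.9),
    deep_atrophy = c(1.3, 0.9), pvs_bg_vol_ml = NA, pvs_cso_vol_ml = NA,
    pvs_bg_count = c(130, 40), pvs_cso_count = c(600, 170),
    pvs_bg_size_ml = c(0.017, 0.005), pvs_cso_size_ml = c(0.018, 0.006),
    pvs_bg_length_vox = c(6.38, 0.44), pvs_cso_length_vox = c(6.39, 0.57),
    pvs_bg_width_vox = c(3.03, 0.27), pvs_cso_width_vox = c(5.70, 0.62))
  all_outcomes <- union(names(outcome_scales), names(params$effect_sizes))

  b_part <- stats::setNames(lapply(all_outcomes, function(o) rnorm(n)),
                            all_outcomes)
  pid_idx <- match(base$participant_id, ppl$participant_id)
  for (o in all_outcomes) {
    beta <- params$effect_sizes[[o]] %||% numeric(0)
    lin <- rep(0, nrow(base))
    for (pn in names(beta)) {
      zcol <- paste0(pn, "_z")
      zval <- if (zcol %in% names(base)) base[[zcol]]
              else as.numeric(scale(base[[pn]]))
      lin <- lin + beta[[pn]] * zval
    }
    v <- max(1 - sum(beta^2), 1e-6)
    y <- lin + sqrt(rho * v) * b_part[[o]][pid_idx] +
      sqrt((1 - rho) * v) * rnorm(nrow(base))
    base[[paste0(o, "_z")]] <- y
    sc <- outcome_scales[[o]]
    if (is.null(sc) || all(is.na(sc))) {
      base[[o]] <- switch(o,
        wmh_volume_ml = exp(log(0.99) + 0.8 * y),
        pvs_bg_vol_ml = exp(log(0.0195 * 50) + 0.35 * y),
        pvs_cso_vol_ml = exp(log(0.03 * 260) + 0.40 * y),
        y)
    } else {
      base[[o]] <- sc[1] + sc[2] * y
    }
  }
  base$fazekas <- pmin(6, pmax(0, round(base$fazekas)))
  base$superficial_atrophy <- pmin(6, pmax(0, round(base$superficial_atrophy)))
  base$deep_atrophy <- pmin(6, pmax(0, round(base$deep_atrophy)))

  # follow-up visit: phenotype change driven by CPAP usage
  fu <- base
  fu$visit <- "followup"
  usage_z <- as.numeric(scale(fu$cpap_usage_hr_per_night))
  for (p in phen_names) {
    delta_beta <- unname(params$change_effects[p])
    if (length(delta_beta) == 0 || is.na(delta_beta)) delta_beta <- 0
    v <- max(1 - delta_beta^2, 1e-6)
    dz <- delta_beta * usage_z +
      sqrt(rho * v) * rnorm(n)[pid_idx] + sqrt((1 - rho) * v) * rnorm(nrow(fu))
    fu[[paste0(p, "_z")]] <- fu[[paste0(p, "_z")]] + dz
    fu[[p]] <- fu[[p]] + scales[[p]][2] * dz
  }
  keep_fu <- rep(TRUE, nrow(fu))
  fu_pid <- match(fu$participant_id, ppl$participant_id)
  for (e in eyes) {
    frac <- unname(params$missing_followup_fraction[e])
    if (is.na(frac)) frac <- params$missing_followup_fraction[[1]]
    drop <- runif(n) < frac
    sel <- fu$eye == e
    keep_fu[sel] <- !drop[fu_pid[sel]]
  }
  fu <- fu[keep_fu, ]

  tab <- rbind(base, fu)
  tab <- tab[order(tab$participant_id, tab$eye, tab$visit), ]
  list(table = tibble::as_tibble(tab),
       true_effects = list(effect_sizes = params$effect_sizes,
                           change_effects = params$change_effects,
                           within_participant_corr = rho))
}
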