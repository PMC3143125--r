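#' Generate a synthetic screening cohort
#'
#' Draws subjects (blood group, Rh, outcome class, covariates) and their
#' longitudinal serum samples under the multiplicative log-normal model
#' described in [cohort_config()]. Every subject contributes a first-window
#' sample; the second and third visits are each retained independently with
#' probability `1 - dropout_prob`, mirroring the attrition of longitudinal
#' screening studies.
#'
#' @param config A [cohort_config()] object.
#' @return A list with two data frames:
#'   * `subjects`: `subject_id`, `blood_group`, `rh`, `outcome`, `bmi`,
#'     `age`, `smoking`, `parity`, `ethnicity`.
#'   * `samples`: `subject_id`, `ga_week`, `concentration_pg_ml`,
#'     `trimester` (1-3, assigned from the sampling window).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 50, seed = 7))
#' table(cohort$subjects$blood_group)
generate_cohort <- function(config) {
  validate_cohort_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  cp <- config$covariate_params

  subjects <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    blood_group = sample(blood_groups(), n, replace = TRUE,
                         prob = config$blood_group_freqs[blood_groups()]),
    rh = ifelse(stats::runif(n) < config$rh_neg_freq, "-", "+"),
    outcome = sample(outcome_classes(), n, replace = TRUE,
                     prob = config$outcome_prevalence[outcome_classes()]),
    bmi = stats::rnorm(n, cp$bmi_mean, cp$bmi_sd),
    age = stats::rnorm(n, cp$age_mean, cp$age_sd),
    smoking = stats::runif(n) < cp$smoking_prob,
    parity = stats::rpois(n, cp$parity_lambda),
    ethnicity = sample(cp$ethnicity_levels, n, replace = TRUE,
                       prob = cp$ethnicity_probs),
    stringsAsFactors = FALSE
  )
  subjects$bmi <- pmax(subjects$bmi, 15)
  subjects$age <- pmax(subjects$age, 16)

  # visit retention: first visit always, later visits subject to dropout
  keep <- cbind(rep(TRUE, n),
                stats::runif(n) >= config$dropout_prob,
                stats::runif(n) >= config$dropout_prob)
  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  subj_row <- idx[, "row"]
  visit <- idx[, "col"]

  mid <- config$window_midweeks
  ga_week <- mid[visit] + sample(-2:2, length(visit), replace = TRUE)

  base <- if (config$baseline_by == "window") {
    config$baseline_medians[visit]
  } else {
    baseline_curve_value(ga_week, mid, config$baseline_medians)
  }
  gmult <- config$group_serum_multipliers[
    cbind(match(subjects$blood_group[subj_row],
                rownames(config$group_serum_multipliers)), visit)]
  dmult <- config$disease_mom_multipliers[
    cbind(match(subjects$outcome[subj_row],
                rownames(config$disease_mom_multipliers)), visit)]

  eff <- covariate_log_effect(subjects[subj_row, , drop = FALSE], config)
  noise <- if (config$log_sd > 0)
    stats::rnorm(length(visit), 0, config$log_sd) else 0

  samples <- data.frame(
    subject_id = subjects$subject_id[subj_row],
    ga_week = as.integer(ga_week),
    concentration_pg_ml = exp(log(base) + log(gmult) + log(dmult) +
                                eff + noise),
    trimester = as.integer(visit),
    stringsAsFactors = FALSE
  )
  list(subjects = subjects, samples = samples)
}

#' Piecewise-linear baseline median curve through the window midpoints
#'
#' Interpolates linearly between the (midweek, median) anchor points and
#' extrapolates with the end-segment slopes outside them.
#'
#' @param week Gestational weeks to evaluate.
#' @param midweeks,medians Anchor points.
#' @return Median concentrations (pg/ml) at `week`.
#' @keywords internal
baseline_curve_value <- function(week, midweeks, medians) {
  slopes <- diff(medians) / diff(midweeks)
  out <- stats::approx(midweeks, medians, xout = week, rule = 2)$y
  lo <- week < midweeks[1]
  hi <- week > midweeks[length(midweeks)]
  out[lo] <- medians[1] + slopes[1] * (week[lo] - midweeks[1])
  out[hi] <- medians[length(medians)] +
    slopes[length(slopes)] * (week[hi] - midweeks[length(midweeks)])
  out
}

#' Centred covariate contribution to log-concentration
#' @keywords internal
covariate_log_effect <- function(subj, config) {
  ce <- config$covariate_effects
  cp <- config$covariate_params
  eth_eff <- ce$ethnicity
  if (is.null(names(eth_eff))) names(eth_eff) <- cp$ethnicity_levels
  ce$bmi * (subj$bmi - cp$bmi_mean) +
    ce$age * (subj$age - cp$age_mean) +
    ce$smoking * (as.numeric(subj$smoking) - cp$smoking_prob) +
    ce$parity * (subj$parity - cp$parity_lambda) +
    unname(eth_eff[subj$ethnicity])
}

#' Generate a synthetic erythrocyte-binding panel
#'
#' Emulates the summarized output of a flow-cytometry binding assay: mean
#' fluorescence intensity (MFI) of labelled PP13 bound to red blood cells of
#' each ABO group over a four-point concentration series, with truncated
#' PP13 (trPP13, lacking the carbohydrate-recognition domain) and BSA as
#' negative controls at the top concentration. Binding follows a monotone
#' saturating curve \eqn{MFI = b_0 + B_g c / (c + K)}; the default
#' group-level capacities reproduce the characteristic affinity ordering
#' AB > A = O > B, the inverse of the serum-level ordering.
#'
#' @param params List of panel parameters:
#'   `bmax` (named per-group saturating amplitudes, fluorescence units),
#'   `k_half` (half-saturation concentration, ug/ml), `baseline`
#'   (non-specific MFI floor shared with the controls), `cv` (coefficient of
#'   variation of replicate experiments; 0 gives a noise-free panel),
#'   `n_experiments` (replicates summarized into mean/SEM), and
#'   `senescent_factor` (capacity multiplier for aged red cells; 1 leaves
#'   the panel untouched).
#' @param seed Integer seed for the replicate noise.
#' @param concentrations PP13 concentrations assayed (ug/ml).
#' @return A data frame (`blood_group`, `conc_ug_ml`, `mean_mfi`, `sem_mfi`,
#'   `ligand`) with one row per group x concentration plus control rows
#'   (`ligand` trPP13 / BSA, `blood_group` NA) at the top concentration.
#' @export
#' @examples
#' panel <- generate_binding_panel(seed = 1)
#' subset(panel, conc_ug_ml == 50 & ligand == "PP13")
generate_binding_panel <- function(params = binding_panel_params(),
                                   seed = 1,
                                   concentrations = c(6.25, 12.5, 25, 50)) {
  stopifnot(all(unlist(params$bmax) > 0), params$k_half > 0,
            params$baseline >= 0, params$cv >= 0)
  set.seed(seed)
  groups <- blood_groups()
  grid <- expand.grid(blood_group = groups, conc_ug_ml = concentrations,
                      stringsAsFactors = FALSE)
  bmax <- unlist(params$bmax)[grid$blood_group] * params$senescent_factor
  mu <- params$baseline +
    bmax * grid$conc_ug_ml / (grid$conc_ug_ml + params$k_half)
  top <- max(concentrations)
  ctrl_mu <- rep(params$baseline, 2)
  mu_all <- c(mu, ctrl_mu)

  n_exp <- params$n_experiments
  reps <- matrix(stats::rnorm(length(mu_all) * n_exp, mean = mu_all,
                              sd = params$cv * mu_all),
                 nrow = length(mu_all))
  mean_mfi <- rowMeans(reps)
  sem_mfi <- apply(reps, 1, stats::sd) / sqrt(n_exp)
  if (params$cv == 0) {            # degenerate noise-free panel
    mean_mfi <- mu_all
    sem_mfi <- rep(0, length(mu_all))
  }

  data.frame(
    blood_group = c(grid$blood_group, NA, NA),
    conc_ug_ml = c(grid$conc_ug_ml, top, top),
    mean_mfi = mean_mfi,
    sem_mfi = sem_mfi,
    ligand = c(rep("PP13", nrow(grid)), "trPP13", "BSA"),
    stringsAsFactors = FALSE
  )
}

#' @rdname generate_binding_panel
#' @export
binding_panel_params <- function() {
  list(bmax = c(O = 600, A = 620, B = 350, AB = 1000),
       k_half = 20, baseline = 60, cv = 0.05,
       n_experiments = 5, senescent_factor = 1)
}
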