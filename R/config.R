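#' Cohort simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [generate_cohort()]. Defaults emulate a prospective longitudinal
#' first-trimester screening cohort: three sampling windows (6-10, 16-20 and
#' 24-28 weeks of gestation), log-normal PP13 concentrations rising with
#' gestation, blood-group-specific serum multipliers (group B highest and AB
#' lowest in the first trimester), trimester-specific disease multipliers for
#' IUGR, preeclampsia and preeclampsia with IUGR, and per-subject dropout of
#' the later visits.
#'
#' Concentrations are generated multiplicatively on the log scale:
#' \deqn{\log C = \log m_w + \log g_{b,t} + \log d_{o,t} + x'\beta + \epsilon}
#' where \eqn{m_w} is the baseline unaffected median for the sampling window,
#' \eqn{g_{b,t}} the blood-group serum multiplier for group \eqn{b} in
#' trimester \eqn{t}, \eqn{d_{o,t}} the disease multiplier for outcome
#' \eqn{o}, \eqn{x'\beta} centred covariate effects and
#' \eqn{\epsilon \sim N(0, \sigma^2)} with \eqn{\sigma} = `log_sd`.
#'
#' @param n_subjects Number of pregnancies to simulate.
#' @param blood_group_freqs Named probabilities for groups O, A, B, AB; must
#'   sum to 1.
#' @param rh_neg_freq Probability of Rh-negative status. Rh is carried as a
#'   grouping variable only; it never enters the concentration model.
#' @param outcome_prevalence Named probabilities for outcome classes
#'   `unaffected`, `IUGR`, `PE`, `PE_IUGR`; must sum to 1. Defaults are the
#'   1006/52/15/5 split of a 1078-subject screening cohort.
#' @param window_midweeks Midpoints (gestational weeks) of the three sampling
#'   windows; strictly increasing. Each window spans the midweek +/- 2 weeks.
#' @param baseline_medians Unaffected median concentration (pg/ml) at each
#'   window; defaults 119, 121, 212.
#' @param group_serum_multipliers 4 x 3 matrix (rows O, A, B, AB; columns
#'   trimester 1-3) of positive serum multipliers. First-trimester defaults
#'   are the observed blood-group MoM medians 0.94 / 1.01 / 1.57 / 0.58, with
#'   the AB deficit attenuating and the B excess persisting by trimester 3.
#' @param disease_mom_multipliers 4 x 3 matrix (rows unaffected, IUGR, PE,
#'   PE_IUGR; columns trimester 1-3) of positive multipliers. Defaults follow
#'   the characteristic pattern of low first-trimester and elevated later
#'   MoMs in the disease groups (e.g. IUGR 0.37, 1.38, 1.22).
#' @param log_sd Standard deviation of log-concentration noise (natural log
#'   scale).
#' @param covariate_params List of distribution parameters for BMI, maternal
#'   age, smoking, parity and ethnicity.
#' @param covariate_effects List of log-scale coefficients linking covariates
#'   to concentration. Numeric covariates act centred at their configured
#'   means; `ethnicity` is a per-level vector.
#' @param dropout_prob Probability that each of visits 2 and 3 is missing,
#'   independently per visit and subject. Visit 1 is always observed.
#' @param baseline_by `"window"` (default): each sample uses its window's
#'   baseline median; `"week"`: the piecewise-linear curve through the
#'   (midweek, median) points, linearly extrapolated at the ends, is
#'   evaluated at the sampled week.
#' @param seed Integer seed; `generate_cohort()` seeds the RNG with it so a
#'   fixed configuration is fully reproducible.
#'
#' @return A list of class `"cohort_config"`.
#' @seealso [generate_cohort()], [generate_binding_panel()]
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 100, seed = 1)
#' cohort <- generate_cohort(cfg)
#' head(cohort$samples)
cohort_config <- function(n_subjects = 1078,
                          blood_group_freqs = c(O = 0.47, A = 0.29,
                                                B = 0.17, AB = 0.07),
                          rh_neg_freq = 0.08,
                          outcome_prevalence = c(unaffected = 1006,
                                                 IUGR = 52,
                                                 PE = 15,
                                                 PE_IUGR = 5) / 1078,
                          window_midweeks = c(8, 18, 26),
                          baseline_medians = c(119, 121, 212),
                          group_serum_multipliers = default_group_multipliers(),
                          disease_mom_multipliers = default_disease_multipliers(),
                          log_sd = 0.4,
                          covariate_params = default_covariate_params(),
                          covariate_effects = default_covariate_effects(),
                          dropout_prob = 0.1,
                          baseline_by = c("window", "week"),
                          seed = NULL) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    blood_group_freqs = blood_group_freqs,
    rh_neg_freq = rh_neg_freq,
    outcome_prevalence = outcome_prevalence,
    window_midweeks = window_midweeks,
    baseline_medians = baseline_medians,
    group_serum_multipliers = group_serum_multipliers,
    disease_mom_multipliers = disease_mom_multipliers,
    log_sd = log_sd,
    covariate_params = covariate_params,
    covariate_effects = covariate_effects,
    dropout_prob = dropout_prob,
    baseline_by = match.arg(baseline_by),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @export
blood_groups <- function() c("O", "A", "B", "AB")

#' @rdname cohort_config
#' @export
outcome_classes <- function() c("unaffected", "IUGR", "PE", "PE_IUGR")

#' Default blood-group serum multipliers (rows O, A, B, AB x trimester 1-3)
#' @return A 4 x 3 positive matrix.
#' @export
default_group_multipliers <- function() {
  m <- rbind(O  = c(0.94, 0.97, 1.00),
             A  = c(1.01, 1.00, 1.00),
             B  = c(1.57, 1.45, 1.45),
             AB = c(0.58, 0.80, 1.00))
  colnames(m) <- paste0("T", 1:3)
  m
}

#' Default disease MoM multipliers (rows outcome x trimester 1-3)
#' @return A 4 x 3 positive matrix.
#' @export
default_disease_multipliers <- function() {
  m <- rbind(unaffected = c(1.00, 1.00, 1.00),
             IUGR       = c(0.37, 1.38, 1.22),
             PE         = c(0.27, 1.71, 1.82),
             PE_IUGR    = c(0.25, 1.91, 1.62))
  colnames(m) <- paste0("T", 1:3)
  m
}

#' @keywords internal
default_covariate_params <- function() {
  list(bmi_mean = 24, bmi_sd = 4,
       age_mean = 29, age_sd = 5,
       smoking_prob = 0.12,
       parity_lambda = 1,
       ethnicity_levels = c("eth1", "eth2", "eth3"),
       ethnicity_probs = c(0.7, 0.2, 0.1))
}

#' @keywords internal
default_covariate_effects <- function() {
  list(bmi = 0.01, age = 0, smoking = 0, parity = 0,
       ethnicity = c(0, 0, 0))
}

#' Validate a cohort configuration
#'
#' @param cfg A `"cohort_config"` list.
#' @return `cfg`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @keywords internal
validate_cohort_config <- function(cfg) {
  check_prob_map <- function(p, what, labels) {
    if (!all(labels %in% names(p)))
      stop(sprintf("%s must be named with %s", what,
                   paste(labels, collapse = ", ")), call. = FALSE)
    p <- p[labels]
    if (any(p < 0))
      stop(sprintf("%s contains negative probabilities", what), call. = FALSE)
    if (abs(sum(p) - 1) > 1e-9)
      stop(sprintf("%s must sum to 1 (got %.12f)", what, sum(p)),
           call. = FALSE)
    p
  }
  cfg_name <- function(x) deparse(substitute(x))
  check_prob_map(cfg$blood_group_freqs, "blood_group_freqs", blood_groups())
  check_prob_map(cfg$outcome_prevalence, "outcome_prevalence",
                 outcome_classes())
  if (cfg$n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (length(cfg$window_midweeks) != 3 ||
      any(diff(cfg$window_midweeks) <= 0))
    stop("window_midweeks must be three strictly increasing weeks",
         call. = FALSE)
  if (length(cfg$baseline_medians) != 3 || any(cfg$baseline_medians <= 0))
    stop("baseline_medians must be three positive values", call. = FALSE)
  for (nm in c("group_serum_multipliers", "disease_mom_multipliers")) {
    m <- cfg[[nm]]
    if (!is.matrix(m) || ncol(m) != 3 || any(m <= 0))
      stop(sprintf("%s must be a positive matrix with 3 trimester columns",
                   nm), call. = FALSE)
  }
  if (!identical(rownames(cfg$group_serum_multipliers), blood_groups()))
    stop("group_serum_multipliers rows must be O, A, B, AB", call. = FALSE)
  if (!identical(rownames(cfg$disease_mom_multipliers), outcome_classes()))
    stop("disease_mom_multipliers rows must be unaffected, IUGR, PE, PE_IUGR",
         call. = FALSE)
  if (cfg$log_sd < 0) stop("log_sd must be >= 0", call. = FALSE)
  if (cfg$dropout_prob < 0 || cfg$dropout_prob > 1)
    stop("dropout_prob must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Read / write a flat cohort configuration file
#'
#' The on-disk format is a YAML document mirroring the fields of
#' [cohort_config()]; matrices are stored as per-row maps.
#'
#' @param path File path.
#' @return `read_cohort_config()` returns a `"cohort_config"`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_mat <- function(x, rows) {
    m <- do.call(rbind, lapply(rows, function(r) unlist(x[[r]])))
    rownames(m) <- rows
    colnames(m) <- paste0("T", 1:3)
    m
  }
  args <- raw
  if (!is.null(raw$blood_group_freqs))
    args$blood_group_freqs <- unlist(raw$blood_group_freqs)
  if (!is.null(raw$outcome_prevalence))
    args$outcome_prevalence <- unlist(raw$outcome_prevalence)
  if (!is.null(raw$group_serum_multipliers))
    args$group_serum_multipliers <- as_mat(raw$group_serum_multipliers,
                                           blood_groups())
  if (!is.null(raw$disease_mom_multipliers))
    args$disease_mom_multipliers <- as_mat(raw$disease_mom_multipliers,
                                           outcome_classes())
  if (!is.null(raw$covariate_effects))
    args$covariate_effects <- lapply(raw$covariate_effects, unlist)
  if (!is.null(raw$covariate_params))
    args$covariate_params <- lapply(raw$covariate_params, unlist)
  do.call(cohort_config, args)
}

#' @rdname read_cohort_config
#' @param cfg A `"cohort_config"` object.
#' @export
write_cohort_config <- function(cfg, path) {
  as_map <- function(m) {
    out <- lapply(seq_len(nrow(m)), function(i) as.list(unname(m[i, ])))
    names(out) <- rownames(m)
    out
  }
  out <- unclass(cfg)
  out$blood_group_freqs <- as.list(cfg$blood_group_freqs)
  out$outcome_prevalence <- as.list(cfg$outcome_prevalence)
  out$group_serum_multipliers <- as_map(cfg$group_serum_multipliers)
  out$disease_mom_multipliers <- as_map(cfg$disease_mom_multipliers)
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}
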