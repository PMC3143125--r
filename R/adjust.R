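#' Sequential covariate adjustment of log-MoMs
#'
#' Fits the covariate adjustment used after gestational-age normalization:
#' for each covariate, in the stated order, log(MoM) is regressed on that
#' covariate among unaffected records by ordinary least squares, the centred
#' fitted component is subtracted, and the residualized values are passed to
#' the next covariate. Because each step removes a centred component, the
#' geometric mean of the MoMs is preserved: the adjustment recenters but
#' does not rescale. A joint multiple-regression mode is available for
#' sensitivity analysis.
#'
#' @param moms Data frame of unaffected records with a `mom` column and the
#'   covariate columns named in `order`.
#' @param order Character vector of covariate column names, fitted in this
#'   order. Default: BMI, ethnicity, smoking, maternal age, parity.
#' @param joint If `TRUE`, fit one joint least-squares model on all
#'   covariates instead of the sequential residualization.
#' @return An object of class `"covariate_model"` storing, per covariate,
#'   the coefficients and centring constants needed to reproduce the
#'   adjustment on new records.
#' @export
fit_covariate_adjustment <- function(moms,
                                     order = c("bmi", "ethnicity", "smoking",
                                               "age", "parity"),
                                     joint = FALSE) {
  missing_cols <- setdiff(c("mom", order), names(moms))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (cv in order) {
    if (anyNA(moms[[cv]])) {
      bad <- unique(moms$subject_id[is.na(moms[[cv]])])
      stop(sprintf("covariate '%s' missing for subject(s): %s", cv,
                   paste(utils::head(bad, 10), collapse = ", ")),
           call. = FALSE)
    }
  }
  y <- log(moms$mom)
  terms <- list()
  if (joint) {
    for (cv in order) terms[[cv]] <- NULL
    terms <- fit_joint_terms(moms, order, y)
  } else {
    for (cv in order) {
      tm <- fit_one_term(moms[[cv]], y, cv)
      y <- y - term_adjustment(tm, moms[[cv]])
      terms[[cv]] <- tm
    }
  }
  structure(list(order = order, terms = terms, joint = joint,
                 n = nrow(moms)),
            class = "covariate_model")
}

#' @keywords internal
fit_one_term <- function(x, y, name) {
  if (is.character(x)) x <- factor(x)
  if (is.logical(x)) x <- as.numeric(x)
  if (is.factor(x)) {
    if (nlevels(droplevels(x)) < 2) {
      warning(sprintf("covariate '%s' is constant; coefficient set to 0",
                      name))
      return(list(type = "factor",
                  adj = stats::setNames(rep(0, nlevels(x)), levels(x))))
    }
    fit <- stats::lm(y ~ x)
    fitted <- stats::fitted(fit)
    adj <- tapply(fitted - mean(fitted), x, mean)
    se <- summary(fit)$coefficients[, "Std. Error"]
    return(list(type = "factor",
                adj = stats::setNames(as.numeric(adj), names(adj)),
                se = se))
  }
  if (stats::sd(x) == 0) {
    warning(sprintf("covariate '%s' is constant; coefficient set to 0",
                    name))
    return(list(type = "numeric", beta = 0, center = mean(x), se = NA_real_))
  }
  fit <- stats::lm(y ~ x)
  list(type = "numeric",
       beta = unname(stats::coef(fit)[2]),
       center = mean(x),
       se = unname(summary(fit)$coefficients[2, "Std. Error"]))
}

#' @keywords internal
fit_joint_terms <- function(moms, order, y) {
  df <- moms[, order, drop = FALSE]
  for (cv in order) {
    if (is.character(df[[cv]])) df[[cv]] <- factor(df[[cv]])
    if (is.logical(df[[cv]])) df[[cv]] <- as.numeric(df[[cv]])
  }
  form <- stats::as.formula(paste("y ~", paste(order, collapse = " + ")))
  fit <- stats::lm(form, data = cbind(df, y = y))
  fitted <- stats::fitted(fit)
  # decompose the joint fit into per-covariate lookup terms
  terms <- list()
  for (cv in order) {
    x <- df[[cv]]
    if (is.factor(x)) {
      cf <- stats::coef(fit)
      eff <- stats::setNames(rep(0, nlevels(x)), levels(x))
      nm <- paste0(cv, levels(x))
      hit <- nm %in% names(cf)
      eff[hit] <- cf[nm[hit]]
      eff[is.na(eff)] <- 0
      p <- table(x) / length(x)
      terms[[cv]] <- list(type = "factor",
                          adj = eff - sum(eff * as.numeric(p)))
    } else {
      b <- stats::coef(fit)[cv]
      if (is.na(b)) b <- 0
      terms[[cv]] <- list(type = "numeric", beta = unname(b),
                          center = mean(x))
    }
  }
  terms
}

#' @keywords internal
term_adjustment <- function(tm, x) {
  if (tm$type == "numeric") {
    if (is.logical(x)) x <- as.numeric(x)
    return(tm$beta * (x - tm$center))
  }
  x <- as.character(x)
  adj <- tm$adj[x]
  unseen <- is.na(adj)
  if (any(unseen)) {
    warning("unseen covariate level(s): ",
            paste(unique(x[unseen]), collapse = ", "),
            "; adjustment 0 applied")
    adj[unseen] <- 0
  }
  unname(adj)
}

#' Apply a fitted covariate adjustment to MoM records
#'
#' @param model A `"covariate_model"` from [fit_covariate_adjustment()].
#' @param moms Data frame with `mom` and the covariate columns.
#' @return `moms` with an added `mom_cov_adj` column,
#'   \eqn{\exp(\log MoM - \sum_k a_k(x_k))}.
#' @export
apply_covariate_adjustment <- function(model, moms) {
  total <- rep(0, nrow(moms))
  for (cv in model$order)
    total <- total + term_adjustment(model$terms[[cv]], moms[[cv]])
  moms$mom_cov_adj <- exp(log(moms$mom) - total)
  moms
}

#' Fit ABO blood-group adjustment factors
#'
#' The factor for group \eqn{g} (optionally within each trimester) is the
#' median covariate-adjusted MoM among unaffected records of that group;
#' dividing by it recenters every group's unaffected median at 1.0. Groups
#' represented by fewer than `min_count` records fall back to a factor of
#' 1.0 with a warning, the convention for very small strata (e.g. an AB
#' stratum of five subjects).
#'
#' @param moms Unaffected records with `mom_cov_adj`, `blood_group` and
#'   (when `per_trimester`) `trimester` columns.
#' @param per_trimester Fit separate factors per trimester (default `TRUE`;
#'   the blood-group effect on serum level varies across pregnancy).
#' @param min_count Minimum records per stratum (default 5).
#' @return An object of class `"bg_factors"`: data frame `blood_group`,
#'   `trimester` (NA when pooled), `factor`, `n`.
#' @export
fit_blood_group_factors <- function(moms, per_trimester = TRUE,
                                    min_count = 5) {
  bad <- setdiff(unique(moms$blood_group), blood_groups())
  if (length(bad) > 0)
    stop("unknown blood group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  tri <- if (per_trimester) sort(unique(moms$trimester)) else NA_integer_
  grid <- expand.grid(blood_group = blood_groups(), trimester = tri,
                      stringsAsFactors = FALSE)
  grid$factor <- 1.0
  grid$n <- 0L
  for (i in seq_len(nrow(grid))) {
    sel <- moms$blood_group == grid$blood_group[i]
    if (per_trimester) sel <- sel & moms$trimester == grid$trimester[i]
    grid$n[i] <- sum(sel)
    if (grid$n[i] >= min_count) {
      grid$factor[i] <- stats::median(moms$mom_cov_adj[sel])
    } else {
      warning(sprintf(
        "blood group %s%s has %d record(s) (< %d); factor fixed at 1.0",
        grid$blood_group[i],
        if (per_trimester) paste0(" (trimester ", grid$trimester[i], ")")
        else "",
        grid$n[i], min_count))
    }
  }
  structure(grid, class = c("bg_factors", "data.frame"))
}

#' Apply blood-group factors to covariate-adjusted MoMs
#'
#' @param moms Records with `mom_cov_adj`, `blood_group` and (for
#'   per-trimester factors) `trimester`.
#' @param factors A `"bg_factors"` object.
#' @return `moms` with an added `mom_abo_adj = mom_cov_adj / factor` column.
#' @export
adjust_for_blood_group <- function(moms, factors) {
  bad <- setdiff(unique(moms$blood_group), blood_groups())
  if (length(bad) > 0)
    stop("unknown blood group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  per_tri <- !all(is.na(factors$trimester))
  key <- if (per_tri)
    paste(moms$blood_group, moms$trimester)
  else moms$blood_group
  fkey <- if (per_tri)
    paste(factors$blood_group, factors$trimester)
  else factors$blood_group
  f <- factors$factor[match(key, fkey)]
  if (anyNA(f))
    stop("no blood-group factor for stratum(s): ",
         paste(unique(key[is.na(f)]), collapse = ", "), call. = FALSE)
  moms$mom_abo_adj <- moms$mom_cov_adj / f
  moms
}

#' Assign trimester labels from the sampling-window design
#'
#' Weeks are assigned to the window (6-10, 16-20, 24-28 by default) whose
#' midweek is nearest; this matches a visit-based design rather than
#' calendar trimester boundaries.
#'
#' @param ga_week Gestational weeks.
#' @param midweeks Window midpoints (default 8, 18, 26).
#' @return Integer trimester labels (1-3).
#' @export
assign_trimester <- function(ga_week, midweeks = c(8, 18, 26)) {
  vapply(ga_week, function(w) which.min(abs(midweeks - w)), integer(1))
}

#' Fit the full MoM pipeline on a cohort
#'
#' Chains the three normalization stages exactly as a screening analysis
#' applies them: (1) a gestational-week median curve fitted on unaffected
#' samples, giving raw MoMs; (2) sequential covariate adjustment (BMI,
#' ethnicity, smoking, maternal age, parity) fitted on unaffected records;
#' (3) ABO blood-group factors fitted on the covariate-adjusted unaffected
#' records. All three components are fitted on unaffected data only and then
#' applied to every record.
#'
#' @param subjects,samples Cohort tables as produced by [generate_cohort()]
#'   or [read_cohort()].
#' @param bin_width,min_count_bin Passed to [fit_median_curve()].
#' @param order,joint Passed to [fit_covariate_adjustment()].
#' @param per_trimester,min_count_group Passed to
#'   [fit_blood_group_factors()].
#' @return An object of class `"mom_fit"`: list with `curve`, `cov_model`,
#'   `bg_factors`, and `moms` (all records with `mom`, `mom_cov_adj`,
#'   `mom_abo_adj`, `trimester`, `outcome`, `blood_group`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 300, seed = 2))
#' fit <- fit_mom_pipeline(cohort$subjects, cohort$samples)
#' with(subset(fit$moms, outcome == "unaffected" & trimester == 1),
#'      median(mom))
fit_mom_pipeline <- function(subjects, samples,
                             bin_width = 1, min_count_bin = 1,
                             order = c("bmi", "ethnicity", "smoking",
                                       "age", "parity"),
                             joint = FALSE,
                             per_trimester = TRUE, min_count_group = 5) {
  dat <- merge_cohort(subjects, samples)
  unaff <- dat[dat$outcome == "unaffected", , drop = FALSE]
  if (nrow(unaff) == 0)
    stop("no unaffected samples to fit on", call. = FALSE)

  curve <- fit_median_curve(unaff, bin_width = bin_width,
                            min_count = min_count_bin)
  unaff <- to_mom(unaff, curve)
  cov_model <- fit_covariate_adjustment(unaff, order = order, joint = joint)
  unaff <- apply_covariate_adjustment(cov_model, unaff)
  bg <- fit_blood_group_factors(unaff, per_trimester = per_trimester,
                                min_count = min_count_group)

  fit <- structure(list(curve = curve, cov_model = cov_model,
                        bg_factors = bg),
                   class = "mom_fit")
  fit$moms <- apply_mom_pipeline(fit, subjects, samples)
  fit
}

#' Apply a fitted MoM pipeline to (possibly new) records
#'
#' @param fit A `"mom_fit"` object.
#' @param subjects,samples Cohort tables; samples outside the fitted curve's
#'   week range raise a lookup error unless `week_fallback`.
#' @param week_fallback Nearest-bin fallback for unseen weeks (see
#'   [curve_value()]).
#' @return Data frame of MoM records (`mom`, `mom_cov_adj`, `mom_abo_adj`).
#' @export
apply_mom_pipeline <- function(fit, subjects, samples,
                               week_fallback = FALSE) {
  dat <- merge_cohort(subjects, samples)
  dat <- to_mom(dat, fit$curve, week_fallback = week_fallback)
  dat <- apply_covariate_adjustment(fit$cov_model, dat)
  adjust_for_blood_group(dat, fit$bg_factors)
}

#' @keywords internal
merge_cohort <- function(subjects, samples) {
  if (!"trimester" %in% names(samples))
    samples$trimester <- assign_trimester(samples$ga_week)
  dat <- merge(samples, subjects, by = "subject_id", sort = FALSE)
  if (nrow(dat) != nrow(samples))
    stop("samples reference unknown subject ids", call. = FALSE)
  dat[order(dat$subject_id, dat$ga_week), , drop = FALSE]
}
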