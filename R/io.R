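#' Read and validate a cohort from delimited text files
#'
#' Loads the subject and sample tables, checks vocabularies and
#' cross-references, and collects all row-level problems into a single
#' error so a malformed file is reported once, not one row at a time.
#'
#' @param subjects_path CSV with columns `subject_id`, `blood_group`, `rh`,
#'   `outcome`, `bmi`, `age`, `smoking`, `parity`, `ethnicity`.
#' @param samples_path CSV with columns `subject_id`, `ga_week`,
#'   `concentration_pg_ml` (an optional `trimester` column is kept).
#' @return List with validated `subjects` and `samples` data frames.
#' @export
read_cohort <- function(subjects_path, samples_path) {
  subjects <- utils::read.csv(subjects_path, stringsAsFactors = FALSE)
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)

  need_subj <- c("subject_id", "blood_group", "rh", "outcome", "bmi",
                 "age", "smoking", "parity", "ethnicity")
  need_samp <- c("subject_id", "ga_week", "concentration_pg_ml")
  if (!all(need_subj %in% names(subjects)))
    stop("subjects file lacks column(s): ",
         paste(setdiff(need_subj, names(subjects)), collapse = ", "),
         call. = FALSE)
  if (!all(need_samp %in% names(samples)))
    stop("samples file lacks column(s): ",
         paste(setdiff(need_samp, names(samples)), collapse = ", "),
         call. = FALSE)

  problems <- character(0)
  bad_bg <- which(!subjects$blood_group %in% blood_groups())
  for (i in bad_bg)
    problems <- c(problems, sprintf(
      "subjects row %d: unknown blood group '%s'", i,
      subjects$blood_group[i]))
  bad_out <- which(!subjects$outcome %in% outcome_classes())
  for (i in bad_out)
    problems <- c(problems, sprintf(
      "subjects row %d: unknown outcome '%s'", i, subjects$outcome[i]))
  dup <- which(duplicated(subjects$subject_id))
  for (i in dup)
    problems <- c(problems, sprintf(
      "subjects row %d: duplicated subject_id '%s'", i,
      subjects$subject_id[i]))
  orphan <- which(!samples$subject_id %in% subjects$subject_id)
  for (i in orphan)
    problems <- c(problems, sprintf(
      "samples row %d: subject_id '%s' not in subjects table", i,
      samples$subject_id[i]))
  nonpos <- which(!(samples$concentration_pg_ml > 0))
  for (i in nonpos)
    problems <- c(problems, sprintf(
      "samples row %d: nonpositive concentration %s", i,
      samples$concentration_pg_ml[i]))
  if (length(problems) > 0)
    stop("cohort validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)

  subjects$smoking <- as.logical(subjects$smoking)
  list(subjects = subjects, samples = samples)
}

#' Write a cohort to delimited text files
#'
#' @param cohort List with `subjects` and `samples` (as from
#'   [generate_cohort()]).
#' @param dir Output directory (created if absent).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, "subjects.csv")
  mp <- file.path(dir, "samples.csv")
  utils::write.csv(cohort$subjects, sp, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$samples, mp, row.names = FALSE, quote = FALSE)
  invisible(c(subjects = sp, samples = mp))
}

#' Distribution-free confidence interval for a median
#'
#' Binomial order-statistic interval: the bounds are the sample order
#' statistics whose ranks cut off the outer \eqn{\alpha/2} binomial(n, 1/2)
#' tails.
#'
#' @param x Numeric sample.
#' @param conf Confidence level (default 0.95).
#' @return Vector `c(median, lower, upper)`.
#' @export
median_ci <- function(x, conf = 0.95) {
  x <- sort(x)
  n <- length(x)
  alpha <- 1 - conf
  lo <- stats::qbinom(alpha / 2, n, 0.5)
  hi <- stats::qbinom(1 - alpha / 2, n, 0.5) + 1
  c(median = stats::median(x),
    lower = x[max(lo, 1)],
    upper = x[min(hi, n)])
}

#' Run the full screening analysis pipeline
#'
#' `simulate -> fit -> evaluate -> report` in one call: generates (or
#' accepts) a cohort, fits the MoM pipeline, evaluates screening
#' performance per disease group before and after blood-group adjustment,
#' and writes `subjects.csv`, `samples.csv`, `moms.csv`,
#' `performance.csv`, `roc_points.csv`, a human-readable `report.txt`
#' (median MoMs with 95% CIs per study group per trimester, and
#' sensitivities/likelihood ratios per disease group per FPR target) and a
#' `manifest.json` recording the configuration, seed, file checksums and
#' per-stage record counts.
#'
#' @param config A [cohort_config()]; ignored when `cohort` is supplied.
#' @param out_dir Output directory.
#' @param seed Integer seed overriding `config$seed`.
#' @param cohort Optional pre-built cohort (list of `subjects`, `samples`).
#' @param loo Use leave-one-out out-of-sample scores for the evaluation
#'   (slower); otherwise in-sample scores are used.
#' @param fpr_targets FPR targets (fractions).
#' @return Invisibly, a list with `fit`, `performance`, `report_path`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir, seed = NULL,
                         cohort = NULL, loo = FALSE,
                         fpr_targets = c(0.15, 0.20)) {
  t0 <- Sys.time()
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(cohort)) cohort <- generate_cohort(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_cohort(cohort, out_dir)

  fit <- suppressWarnings(fit_mom_pipeline(cohort$subjects,
                                           cohort$samples))
  moms <- fit$moms
  utils::write.csv(
    moms[, c("subject_id", "ga_week", "trimester", "concentration_pg_ml",
             "mom", "mom_cov_adj", "mom_abo_adj", "outcome",
             "blood_group")],
    file.path(out_dir, "moms.csv"), row.names = FALSE, quote = FALSE)

  scores <- if (loo) {
    suppressWarnings(loo_scores(cohort$subjects, cohort$samples))
  } else {
    moms[moms$trimester == 1, , drop = FALSE]
  }
  # one score per subject: the first-trimester sample
  scores <- scores[!duplicated(scores$subject_id), , drop = FALSE]

  groups <- list(IUGR = "IUGR",
                 preeclampsia = c("PE", "PE_IUGR"),
                 preeclampsia_with_IUGR = "PE_IUGR")
  perf <- list()
  roc_pts <- list()
  for (gname in names(groups)) {
    sel <- scores$outcome %in% c("unaffected", groups[[gname]])
    sub <- scores[sel, , drop = FALSE]
    labels <- sub$outcome %in% groups[[gname]]
    if (!any(labels)) next
    for (state in c("mom_cov_adj", "mom_abo_adj")) {
      p <- screening_performance(sub[[state]], labels, direction = "low",
                                 fpr_targets = fpr_targets)
      p <- cbind(disease_group = gname,
                 adjustment = if (state == "mom_abo_adj")
                   "ABO_adjusted" else "unadjusted",
                 p)
      perf[[paste(gname, state)]] <- p
      rc <- roc_curve(sub[[state]], labels, direction = "low")
      roc_pts[[paste(gname, state)]] <- cbind(
        disease_group = gname,
        adjustment = if (state == "mom_abo_adj") "ABO_adjusted"
        else "unadjusted",
        as.data.frame(rc))
    }
  }
  performance <- do.call(rbind, perf)
  rownames(performance) <- NULL
  utils::write.csv(performance, file.path(out_dir, "performance.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, roc_pts),
                   file.path(out_dir, "roc_points.csv"),
                   row.names = FALSE, quote = FALSE)

  report_path <- file.path(out_dir, "report.txt")
  writeLines(render_report(moms, performance), report_path)

  manifest <- list(
    tool = "pp13screen",
    version = as.character(utils::packageVersion("pp13screen")),
    seed = config$seed,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    scoring = if (loo) "leave_one_out" else "in_sample",
    record_counts = list(subjects = nrow(cohort$subjects),
                         samples = nrow(cohort$samples),
                         moms = nrow(moms),
                         scored_subjects = nrow(scores)),
    checksums = as.list(tools::md5sum(
      c(paths, moms = file.path(out_dir, "moms.csv"),
        performance = file.path(out_dir, "performance.csv"))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fit = fit, performance = performance,
                 report_path = report_path, manifest = manifest))
}

#' @keywords internal
render_report <- function(moms, performance) {
  lines <- c("PP13 MoM screening report", "=========================", "")
  lines <- c(lines,
             "Median MoM (95% CI) by study group and trimester:", "")
  grp_order <- outcome_classes()
  for (g in grp_order) {
    lines <- c(lines, sprintf("%s:", g))
    for (tri in sort(unique(moms$trimester))) {
      sel <- moms$outcome == g & moms$trimester == tri
      if (!any(sel)) next
      raw <- median_ci(moms$mom[sel])
      adj <- median_ci(moms$mom_abo_adj[sel])
      lines <- c(lines, sprintf(
        "  trimester %d (n=%4d): MoM %.2f (%.2f-%.2f), ABO-adjusted %.2f (%.2f-%.2f)",
        tri, sum(sel), raw[1], raw[2], raw[3], adj[1], adj[2], adj[3]))
    }
  }
  lines <- c(lines, "",
             "First-trimester screening performance (low MoM positive):",
             "")
  for (i in seq_len(nrow(performance))) {
    p <- performance[i, ]
    lines <- c(lines, sprintf(
      "  %-22s %-12s FPR %2.0f%%: sens %5.1f%%  LR+ %5.2f  LR- %5.2f  overall LR %6.2f  AUC %.3f",
      p$disease_group, p$adjustment, p$fpr_target, p$sensitivity,
      p$positive_lr, p$negative_lr, p$overall_lr, p$auc))
  }
  lines
}
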