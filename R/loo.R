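#' Leave-one-out out-of-sample risk scores
#'
#' Computes each subject's adjusted MoM from models fitted with that subject
#' excluded: the gestational-week median curve, the sequential covariate
#' adjustment and the blood-group factors are all refitted on the remaining
#' subjects, then applied to the held-out subject's samples. This removes
#' the over-fitting bias of scoring a subject with models her own data
#' helped estimate. Excluding a subject can empty a small stratum; the
#' usual fallbacks (bin merging, factor 1.0) then apply.
#'
#' @param subjects,samples Cohort tables.
#' @param trimester_filter Restrict scoring to samples of this trimester
#'   (default 1, the screening visit); `NULL` scores all samples.
#' @param ... Passed to [fit_mom_pipeline()] (adjustment order, joint mode,
#'   per-trimester factors, stratum minima).
#' @return Data frame with one row per scored sample: `subject_id`,
#'   `ga_week`, `trimester`, `mom`, `mom_cov_adj`, `mom_abo_adj`, `outcome`,
#'   `blood_group`. Deterministic given its inputs.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 60, seed = 3))
#' scores <- loo_scores(cohort$subjects, cohort$samples)
#' head(scores)
loo_scores <- function(subjects, samples, trimester_filter = 1, ...) {
  if (!"trimester" %in% names(samples))
    samples$trimester <- assign_trimester(samples$ga_week)
  target <- samples
  if (!is.null(trimester_filter))
    target <- target[target$trimester %in% trimester_filter, , drop = FALSE]

  out <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    own <- target[target$subject_id == sid, , drop = FALSE]
    if (nrow(own) == 0) next
    rest_subj <- subjects[subjects$subject_id != sid, , drop = FALSE]
    rest_samp <- samples[samples$subject_id != sid, , drop = FALSE]
    fit <- suppressWarnings(
      fit_mom_pipeline(rest_subj, rest_samp, ...))
    scored <- apply_mom_pipeline(fit, subjects[i, , drop = FALSE], own,
                                 week_fallback = TRUE)
    out[[i]] <- scored[, c("subject_id", "ga_week", "trimester", "mom",
                           "mom_cov_adj", "mom_abo_adj", "outcome",
                           "blood_group")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
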