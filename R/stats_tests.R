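#' Nonparametric group comparisons
#'
#' Thin wrapper over the standard rank tests used for cross-sectional
#' comparisons of serum values: Wilcoxon rank-sum (identically the
#' Mann-Whitney U test) for two groups and Kruskal-Wallis for two or more.
#' Mid-ranks handle ties; for two groups the Kruskal-Wallis statistic is the
#' square of the standardized rank-sum statistic, so the tests agree.
#'
#' @param values Numeric measurements.
#' @param groups Group labels, same length as `values`.
#' @param test One of `"wilcoxon_rank_sum"`, `"mann_whitney"`,
#'   `"kruskal_wallis"`.
#' @return List with `test`, `groups`, `statistic`, `p_value`.
#' @export
#' @examples
#' rank_test(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3),
#'           "mann_whitney")$p_value
rank_test <- function(values, groups,
                      test = c("wilcoxon_rank_sum", "mann_whitney",
                               "kruskal_wallis")) {
  test <- match.arg(test)
  groups <- as.character(groups)
  tab <- table(groups)
  if (any(tab == 0) || length(tab) < 2)
    stop("need at least two non-empty groups", call. = FALSE)
  if (test %in% c("wilcoxon_rank_sum", "mann_whitney")) {
    if (length(tab) != 2)
      stop("two-sample rank test requires exactly two groups",
           call. = FALSE)
    g <- names(tab)
    ht <- suppressWarnings(
      stats::wilcox.test(values[groups == g[1]], values[groups == g[2]],
                         exact = FALSE, correct = FALSE))
  } else {
    ht <- stats::kruskal.test(values, factor(groups))
  }
  list(test = test, groups = names(tab),
       statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Paired bootstrap comparison of two sensitivities
#'
#' Tests whether two scores for the same subjects differ in sensitivity at
#' a fixed false-positive rate (e.g. the unadjusted vs the blood-group
#' adjusted MoM). Subjects are resampled with replacement in pairs, each
#' replicate's sensitivity difference is recorded, and a two-sided p-value
#' is formed from the bootstrap distribution's tail beyond zero (with the
#' usual +1 continuity correction).
#'
#' @param scores_a,scores_b Paired score vectors for the same subjects.
#' @param labels Case indicator.
#' @param fpr_target Target FPR (fraction).
#' @param direction Score direction (see [roc_curve()]).
#' @param n_boot Bootstrap replicates (default 2000; below 100 a warning is
#'   issued).
#' @param seed Integer seed making the resampling deterministic.
#' @return List with `diff` (observed sensitivity difference, percentage
#'   points, b minus a), `p_value`, `n_boot`.
#' @export
compare_sensitivities <- function(scores_a, scores_b, labels,
                                  fpr_target = 0.15,
                                  direction = c("low", "high"),
                                  n_boot = 2000, seed = 1) {
  direction <- match.arg(direction)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must have equal length",
         call. = FALSE)
  if (n_boot < 100)
    warning("n_boot < 100 gives an unstable p-value")
  labels <- as.logical(labels)
  sens <- function(s, l) {
    sensitivity_at_fpr(roc_curve(s, l, direction), fpr_target)
  }
  obs <- sens(scores_b, labels) - sens(scores_a, labels)
  set.seed(seed)
  diffs <- numeric(n_boot)
  n <- length(labels)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(labels[idx]) && any(!labels[idx])) break
    }
    diffs[b] <- sens(scores_b[idx], labels[idx]) -
      sens(scores_a[idx], labels[idx])
  }
  # two-sided: double the smaller tail of the centred bootstrap distribution
  centred <- diffs - mean(diffs)
  p_hi <- (sum(centred >= abs(obs)) + 1) / (n_boot + 1)
  p_lo <- (sum(centred <= -abs(obs)) + 1) / (n_boot + 1)
  p <- min(1, 2 * min(p_lo, p_hi))
  list(diff = obs, p_value = p, n_boot = n_boot)
}
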