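#' ROC curve for a screening score
#'
#' Builds the receiver-operating-characteristic curve of a score against
#' binary outcome labels. `direction = "low"` (the first-trimester
#' convention, where disease lowers the MoM) treats low scores as screen
#' positive; `"high"` treats high scores as positive. Tied scores are
#' collapsed into a single step, and the endpoints (0,0) and (1,1) are
#' always present.
#'
#' @param scores Numeric scores, one per subject.
#' @param labels Logical or 0/1 vector; `TRUE`/1 marks cases.
#' @param direction `"low"` or `"high"`: which extreme of the score is
#'   screen positive.
#' @return An object of class `"roc_curve"`: data frame with `threshold`,
#'   `tpr`, `fpr`; attributes `n_cases`, `n_controls`, `direction`.
#' @export
#' @examples
#' r <- roc_curve(c(0.2, 0.4, 0.9, 1.1), c(TRUE, TRUE, FALSE, FALSE),
#'                direction = "low")
#' auc(r)
roc_curve <- function(scores, labels, direction = c("low", "high")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels lengths differ", call. = FALSE)
  if (anyNA(scores) || anyNA(labels))
    stop("scores and labels must not contain NA", call. = FALSE)
  n_case <- sum(labels)
  n_ctrl <- sum(!labels)
  if (n_case == 0 || n_ctrl == 0)
    stop("need at least one case and one control", call. = FALSE)

  s <- if (direction == "low") -scores else scores
  thr <- sort(unique(s), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(s >= t & labels), numeric(1))
  fp <- vapply(thr, function(t) sum(s >= t & !labels), numeric(1))
  out <- data.frame(threshold = c(NA, if (direction == "low") -thr else thr,
                                  NA),
                    tpr = c(0, tp / n_case, 1),
                    fpr = c(0, fp / n_ctrl, 1))
  out <- out[!duplicated(out[, c("tpr", "fpr")]), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_cases = n_case, n_controls = n_ctrl,
            direction = direction,
            class = c("roc_curve", "data.frame"))
}

#' Area under a ROC curve
#'
#' Trapezoidal area; tied scores (collapsed steps) receive half credit,
#' making the result equal to the pairwise probability
#' \eqn{P(case > control) + P(case = control)/2}, i.e. the Mann-Whitney
#' U statistic scaled by \eqn{n_1 n_2}.
#'
#' @param curve A `"roc_curve"`.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(curve) {
  fpr <- curve$fpr
  tpr <- curve$tpr
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Sensitivity at a fixed false-positive rate
#'
#' Uses the conservative step convention: the largest true-positive rate
#' among realized operating points whose FPR does not exceed the target; no
#' interpolation between points.
#'
#' @param curve A `"roc_curve"`.
#' @param fpr_target Target FPR as a fraction (e.g. 0.15 or 0.20).
#' @return Sensitivity in percent.
#' @export
sensitivity_at_fpr <- function(curve, fpr_target) {
  ok <- curve$fpr <= fpr_target + 1e-12
  100 * max(curve$tpr[ok])
}

#' Realized FPR at the operating point used for a sensitivity target
#' @rdname sensitivity_at_fpr
#' @export
realized_fpr <- function(curve, fpr_target) {
  ok <- curve$fpr <= fpr_target + 1e-12
  best <- max(curve$tpr[ok])
  100 * max(curve$fpr[ok & curve$tpr == best])
}

#' Likelihood ratios from sensitivity and false-positive rate
#'
#' \eqn{LR^+ = sens/(1-spec)}, \eqn{LR^- = (1-sens)/spec} and the overall
#' LR, their ratio — a single summary of test informativeness. In reporting
#' mode (`report = TRUE`) LR+ and LR- are rounded to two decimals before
#' the overall ratio is formed, mirroring how screening tables are printed;
#' full precision is the default.
#'
#' @param sensitivity Sensitivity in percent (0-100).
#' @param fpr False-positive rate in percent (0-100, exclusive of 0 and
#'   100 for finite ratios).
#' @param report Round LR+ and LR- to two decimals before taking their
#'   ratio.
#' @return List with `positive_lr`, `negative_lr`, `overall_lr`.
#' @export
#' @examples
#' likelihood_ratios(28, 15)   # LR+ 1.87, LR- 0.85, overall ~2.2
likelihood_ratios <- function(sensitivity, fpr, report = FALSE) {
  if (sensitivity < 0 || sensitivity > 100)
    stop("sensitivity must be in [0, 100] percent", call. = FALSE)
  if (fpr <= 0 || fpr >= 100) {
    if (fpr == 0 && sensitivity > 0)
      stop("FPR = 0 with positive sensitivity: LR+ is infinite",
           call. = FALSE)
    stop("fpr must be in (0, 100) percent", call. = FALSE)
  }
  pos <- sensitivity / fpr
  neg <- (100 - sensitivity) / (100 - fpr)
  if (report) {
    pos <- round(pos, 2)
    neg <- round(neg, 2)
  }
  list(positive_lr = pos, negative_lr = neg, overall_lr = pos / neg)
}

#' Screening performance summary at fixed FPR targets
#'
#' @param scores,labels,direction As in [roc_curve()].
#' @param fpr_targets FPR targets as fractions (default 0.15 and 0.20).
#' @return A data frame with one row per target: `fpr_target`,
#'   `sensitivity` (percent), `realized_fpr` (percent), `positive_lr`,
#'   `negative_lr`, `overall_lr`, `auc`.
#' @export
screening_performance <- function(scores, labels,
                                  direction = c("low", "high"),
                                  fpr_targets = c(0.15, 0.20)) {
  curve <- roc_curve(scores, labels, direction)
  a <- auc(curve)
  rows <- lapply(fpr_targets, function(f) {
    sens <- sensitivity_at_fpr(curve, f)
    lr <- likelihood_ratios(sens, 100 * f)
    data.frame(fpr_target = 100 * f, sensitivity = sens,
               realized_fpr = realized_fpr(curve, f),
               positive_lr = lr$positive_lr, negative_lr = lr$negative_lr,
               overall_lr = lr$overall_lr, auc = a)
  })
  do.call(rbind, rows)
}
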