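#' Longitudinal change rate between two visits
#'
#' The per-week change statistic \eqn{(X_2 - X_1) / (W_2 - W_1)} for a pair
#' of serum values (concentration or MoM) measured at gestational weeks
#' \eqn{W_1} and \eqn{W_2}.
#'
#' @param x1,x2 Values at the first and second visit.
#' @param w1,w2 Gestational weeks of the visits; `w1 != w2`.
#' @return Change per week, in the units of `x1`/`x2`.
#' @export
#' @examples
#' change_rate(119, 212, 8, 26)  # 93/18 pg/ml per week
change_rate <- function(x1, x2, w1, w2) {
  if (any(w1 == w2))
    stop("change rate undefined for identical weeks (W1 = W2)",
         call. = FALSE)
  (x2 - x1) / (w2 - w1)
}

#' Regression line through per-window medians
#'
#' Ordinary least squares fitted on the (midweek, median) points of each
#' sampling window — the slope summarizes how fast the median serum level
#' rises across pregnancy and is the statistic on which blood-group trends
#' are compared (steepest in group B).
#'
#' @param midweek Window midpoints (weeks); at least two distinct values.
#' @param median_value Median serum values at those midpoints.
#' @return List with `slope` (units per week), `intercept`, and `residuals`.
#' @export
#' @examples
#' median_slope(c(8, 18, 26), c(119, 121, 212))$slope
median_slope <- function(midweek, median_value) {
  if (length(midweek) < 2 || length(unique(midweek)) < 2)
    stop("median_slope needs at least two distinct midweeks", call. = FALSE)
  if (length(midweek) != length(median_value))
    stop("midweek and median_value lengths differ", call. = FALSE)
  fit <- stats::lm(median_value ~ midweek)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residuals = unname(stats::residuals(fit)))
}
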