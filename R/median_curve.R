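#' Fit a gestational-week-specific median curve
#'
#' Computes the median concentration among unaffected samples within
#' gestational-week bins. The curve is the denominator of the MoM (multiple
#' of the median) transformation: a sample's MoM is its concentration
#' divided by the curve value at its week. Medians use the usual midpoint
#' convention for even counts; bins holding fewer than `min_count` samples
#' are merged with the nearest occupied neighbour bin (nearer week wins,
#' lower week on ties) before medians are taken.
#'
#' @param samples Data frame with `ga_week` and `concentration_pg_ml`,
#'   already restricted to unaffected subjects.
#' @param bin_width Width of the gestational-age bins in weeks (default 1,
#'   i.e. weekly medians).
#' @param min_count Minimum samples per bin before merging (default 1, no
#'   merging).
#' @return An object of class `"median_curve"`: a data frame with `ga_week`
#'   (bin midpoint week), `median_pg_ml` and `n`, plus a `bin_of` attribute
#'   mapping each observed week to its bin.
#' @export
#' @examples
#' s <- data.frame(ga_week = c(8, 8, 8, 9),
#'                 concentration_pg_ml = c(80, 100, 120, 95))
#' curve <- fit_median_curve(s)
#' curve_value(curve, 8)
fit_median_curve <- function(samples, bin_width = 1, min_count = 1) {
  if (nrow(samples) == 0)
    stop("cannot fit a median curve on zero samples", call. = FALSE)
  if (any(samples$concentration_pg_ml <= 0))
    stop("concentrations must be positive", call. = FALSE)
  wk <- samples$ga_week
  bin <- floor(wk / bin_width) * bin_width
  tab <- table(bin)
  bins <- as.numeric(names(tab))
  counts <- as.integer(tab)

  # merge undersized bins into their nearest occupied neighbour
  assign_to <- stats::setNames(bins, bins)
  if (length(bins) > 1) {
    repeat {
      sizes <- tapply(counts, assign_to[as.character(bins)], sum)
      small <- names(sizes)[sizes < min_count]
      if (length(small) == 0) break
      s <- as.numeric(small[1])
      others <- as.numeric(names(sizes)[names(sizes) != small[1]])
      if (length(others) == 0) break
      target <- others[order(abs(others - s), others)][1]
      assign_to[assign_to == s] <- target
    }
  }
  eff_bin <- assign_to[as.character(bin)]

  med <- tapply(samples$concentration_pg_ml, eff_bin, stats::median)
  n_per <- tapply(samples$concentration_pg_ml, eff_bin, length)
  curve <- data.frame(ga_week = as.numeric(names(med)),
                      median_pg_ml = as.numeric(med),
                      n = as.integer(n_per))
  curve <- curve[order(curve$ga_week), ]
  rownames(curve) <- NULL
  attr(curve, "bin_of") <- stats::setNames(as.numeric(eff_bin),
                                           as.character(bin))
  attr(curve, "bin_width") <- bin_width
  class(curve) <- c("median_curve", "data.frame")
  curve
}

#' Look up the median-curve value at given gestational weeks
#'
#' @param curve A `"median_curve"` from [fit_median_curve()].
#' @param ga_week Weeks to look up; each must fall in a bin the curve was
#'   fitted on (after any merging), unless `fallback = TRUE`.
#' @param fallback If `TRUE`, a week with no fitted bin falls back to the
#'   nearest fitted bin (lower week on ties) instead of raising an error —
#'   the convention used when scoring held-out subjects.
#' @return Median concentrations (pg/ml).
#' @export
curve_value <- function(curve, ga_week, fallback = FALSE) {
  bw <- attr(curve, "bin_width")
  bin_of <- attr(curve, "bin_of")
  bin <- floor(ga_week / bw) * bw
  eff <- bin_of[as.character(bin)]
  missing <- is.na(eff)
  if (any(missing)) {
    if (!fallback)
      stop(sprintf("no median available for gestational week(s): %s",
                   paste(unique(ga_week[missing]), collapse = ", ")),
           call. = FALSE)
    fitted_bins <- curve$ga_week
    eff[missing] <- vapply(bin[missing], function(b) {
      fitted_bins[order(abs(fitted_bins - b), fitted_bins)][1]
    }, numeric(1))
  }
  idx <- match(eff, curve$ga_week)
  curve$median_pg_ml[idx]
}

#' Convert concentrations to multiples of the median (MoM)
#'
#' Divides each sample's concentration by the unaffected median for its
#' gestational week. A MoM of 1.0 means typical for that week; disease
#' groups characteristically show MoM < 1 in the first trimester and > 1
#' later.
#'
#' @param samples Data frame with `subject_id`, `ga_week`,
#'   `concentration_pg_ml` and optionally `trimester`.
#' @param curve A `"median_curve"` covering every sampled week.
#' @param week_fallback Passed to [curve_value()] as `fallback`.
#' @return `samples` with an added `mom` column.
#' @export
#' @examples
#' s <- data.frame(subject_id = "S1", ga_week = 8,
#'                 concentration_pg_ml = 42)
#' curve <- fit_median_curve(
#'   data.frame(ga_week = 8, concentration_pg_ml = 119))
#' to_mom(s, curve)$mom  # 42/119
to_mom <- function(samples, curve, week_fallback = FALSE) {
  if (any(samples$concentration_pg_ml <= 0))
    stop("concentrations must be positive", call. = FALSE)
  samples$mom <- samples$concentration_pg_ml /
    curve_value(curve, samples$ga_week, fallback = week_fallback)
  samples
}

#' @export
print.median_curve <- function(x, ...) {
  cat(sprintf("Gestational-week median curve (%d bins, %d samples)\n",
              nrow(x), sum(x$n)))
  print(as.data.frame(x), ...)
  invisible(x)
}
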