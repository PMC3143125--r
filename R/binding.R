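#' Proportional profile across blood groups
#'
#' Expresses per-group values (median serum concentrations in one
#' trimester, or binding MFIs at one ligand concentration) as percent
#' shares of the four-group total, the representation in which serum and
#' red-cell-binding profiles can be compared directly.
#'
#' @param values Named positive values, one per blood group.
#' @return Named shares in percent, summing to 100.
#' @export
#' @examples
#' proportional_profile(c(O = 89, A = 114, B = 183, AB = 60))
proportional_profile <- function(values) {
  if (any(values <= 0))
    stop("all values must be positive", call. = FALSE)
  100 * values / sum(values)
}

#' Inverse-mirror score between serum and binding profiles
#'
#' Rank correlation (Spearman, with mid-ranks for ties) between the serum
#' share and the binding share of each blood group. Strong sequestration of
#' the lectin on red cells of a group depresses its serum level, so an
#' inverse-mirror relation shows up as a score near -1.
#'
#' @param serum_profile,binding_profile Named shares (or raw positive
#'   values) over the same four blood groups.
#' @return Rank correlation in \[-1, 1\]. A constant profile is degenerate:
#'   the score is reported as 0 with attribute `degenerate = TRUE`.
#' @export
#' @examples
#' serum <- c(O = 0.94, A = 1.01, B = 1.57, AB = 0.58)
#' binding <- c(O = 600, A = 620, B = 350, AB = 1000)
#' inverse_mirror_score(serum, binding)
inverse_mirror_score <- function(serum_profile, binding_profile) {
  g <- names(serum_profile)
  if (is.null(g) || !setequal(g, names(binding_profile)))
    stop("profiles must be named over the same blood groups", call. = FALSE)
  s <- serum_profile[g]
  b <- binding_profile[g]
  if (stats::sd(s) == 0 || stats::sd(b) == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  unname(stats::cor(rank(s), rank(b), method = "pearson"))
}

#' Specific binding of PP13 relative to controls
#'
#' Fold-change of each blood group's MFI at the top ligand concentration
#' over the mean of the negative-control rows (truncated PP13 lacking the
#' carbohydrate-recognition domain, and BSA). Folds well above 1 indicate
#' binding mediated specifically by the CRD.
#'
#' @param panel Binding panel data frame as from
#'   [generate_binding_panel()] (columns `blood_group`, `conc_ug_ml`,
#'   `mean_mfi`, `ligand`).
#' @return Named fold-over-control values per blood group.
#' @export
specific_binding_ratio <- function(panel) {
  ctrl <- panel$ligand %in% c("trPP13", "BSA")
  if (!any(ctrl))
    stop("panel contains no trPP13/BSA control rows", call. = FALSE)
  ctrl_mfi <- mean(panel$mean_mfi[ctrl])
  pp13 <- panel[panel$ligand == "PP13", , drop = FALSE]
  top <- max(pp13$conc_ug_ml)
  at_top <- pp13[pp13$conc_ug_ml == top, , drop = FALSE]
  stats::setNames(at_top$mean_mfi / ctrl_mfi, at_top$blood_group)
}
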