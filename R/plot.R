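#' @include stats.R
NULL

#' Plot a p-value-versus-frequency deficit profile
#'
#' Renders the per-bin p-value profile of one feature and condition as a
#' bar chart over 1..40 Hz with a dashed line at the significance level,
#' the conventional reading of a per-frequency deficit profile. Bars are
#' shaded by band membership.
#'
#' @param report a [DeficitReport-class] containing bin-scope results for
#'   the requested feature and condition.
#' @param feature feature name (default the first present).
#' @param condition condition label (default the first present).
#' @param alpha significance level line (default from the report).
#' @param useAdjusted plot Bonferroni-adjusted instead of raw p-values.
#' @return Invisibly, the vector of plotted p-values.
#' @export
plotDeficitProfile <- function(report, feature = NULL, condition = NULL,
                               alpha = NULL, useAdjusted = FALSE) {
  stopifnot(is(report, "DeficitReport"))
  res <- report@results
  if (is.null(feature)) feature <- res$feature[1]
  if (is.null(condition)) condition <- res$condition[1]
  if (is.null(alpha)) alpha <- report@meta$alpha %||% 0.05
  res <- res[res$feature == feature & res$condition == condition &
             startsWith(res$scope, "bin:"), , drop = FALSE]
  if (!nrow(res)) stop("no bin-scope results for this feature/condition")
  bins <- as.integer(sub("bin:", "", res$scope))
  p <- if (useAdjusted) res$p_bonferroni else res$p_raw
  p <- p[order(bins)]
  bins <- sort(bins)
  bandCol <- c(delta = "#4477AA", theta = "#66CCEE", alpha = "#228833",
               beta = "#CCBB44", gamma = "#EE6677")
  colFor <- function(b) {
    if (b <= 4) bandCol["delta"] else if (b <= 8) bandCol["theta"]
    else if (b <= 12) bandCol["alpha"] else if (b <= 30) bandCol["beta"]
    else bandCol["gamma"]
  }
  graphics::barplot(p, names.arg = bins,
                    col = vapply(bins, colFor, ""),
                    border = NA, space = 0.2,
                    xlab = "Frequency (Hz)", ylab = "p-value",
                    main = sprintf("%s / %s", feature, condition),
                    ylim = c(0, max(1, max(p, na.rm = TRUE))))
  graphics::abline(h = alpha, lty = 2)
  invisible(p)
}
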