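#' Volcano plot table
#'
#' Plot-ready rows of log2 fold change against -log10 raw p, categorised
#' with the figure-style thresholds: `up` if `lfc > count_lfc_cut` and
#' `p < count_p_cut`, `down` if `lfc < -count_lfc_cut` and
#' `p < count_p_cut`, `ns` otherwise. Zero p-values are clamped to the
#' smallest positive double with a message. Dashed-line positions
#' (±`count_lfc_cut`, `-log10(count_p_cut)`) are attached as attribute
#' `thresholds`.
#'
#' @param table A `de_table` (or data frame with `protein`, `lfc`, `p`).
#' @param config An [analysis_config()].
#' @return Data frame: `protein`, `lfc`, `neg_log10_p`, `category`.
#' @export
volcano_table <- function(table, config = analysis_config()) {
  p <- table$p
  if (any(p == 0)) {
    message(sum(p == 0), " zero p-value(s) clamped for -log10")
    p[p == 0] <- .Machine$double.xmin
  }
  up <- table$lfc > config$count_lfc_cut & p < config$count_p_cut
  down <- table$lfc < -config$count_lfc_cut & p < config$count_p_cut
  out <- data.frame(
    protein = table$protein,
    lfc = table$lfc,
    neg_log10_p = -log10(p),
    category = ifelse(up, "up", ifelse(down, "down", "ns")),
    stringsAsFactors = FALSE
  )
  attr(out, "thresholds") <- list(
    lfc = c(-config$count_lfc_cut, config$count_lfc_cut),
    neg_log10_p = -log10(config$count_p_cut)
  )
  out
}

#' Boxplot summary statistics
#'
#' Five-number-style summary with Tukey-style whiskers: quartiles by
#' linear interpolation between order statistics
#' ([stats::quantile()] type 7), whiskers at the furthest data point
#' within `whisker_mult * IQR` of the box, values beyond the whisker
#' fences reported as outliers.
#'
#' @param values Numeric vector (length >= 1, NAs dropped).
#' @param whisker_mult Whisker reach in IQR multiples (default 1.5).
#' @return List: `median`, `q1`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
boxplot_stats <- function(values, whisker_mult = 1.5) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("boxplot_stats needs at least one value")
  qs <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- qs[3L] - qs[1L]
  lo_fence <- qs[1L] - whisker_mult * iqr
  hi_fence <- qs[3L] + whisker_mult * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  list(
    median = qs[2L], q1 = qs[1L], q3 = qs[3L], iqr = iqr,
    whisker_low = min(inside), whisker_high = max(inside),
    outliers = sort(values[values < lo_fence | values > hi_fence])
  )
}

#' Relative expression by the delta-delta-Ct method
#'
#' qPCR fold change of a target gene in a case sample relative to a
#' control sample, each normalised to a housekeeping (reference) gene:
#' `fold = 2^-((Ct_target_case - Ct_ref_case) -
#' (Ct_target_ctrl - Ct_ref_ctrl))`.
#'
#' @param ct_target_case,ct_ref_case Target and reference-gene Ct in the
#'   case condition.
#' @param ct_target_ctrl,ct_ref_ctrl Target and reference-gene Ct in the
#'   control condition.
#' @return Fold change (1 = no change, 2 = doubling). Vectorised.
#' @examples
#' ddct_fold_change(24, 18, 25, 18)  # one cycle earlier in case -> 2
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(is.finite(ct_target_case), is.finite(ct_ref_case),
            is.finite(ct_target_ctrl), is.finite(ct_ref_ctrl))
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
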