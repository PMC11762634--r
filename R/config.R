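#' Analysis configuration
#'
#' Collects every tunable constant of the pipeline in one validated object.
#' Defaults reproduce the published procedure: missing values in replicate
#' groups with at most one detection are drawn from a Gaussian of width
#' 0.3 sample standard deviations, shifted left of the sample mean by 2.5
#' sample standard deviations; 20 imputation cycles; significance requires
#' an absolute log2 fold change of at least 1 and an adjusted p-value of at
#' most 0.05. The figure-style counting thresholds (|log2FC| > 0.5,
#' raw p < 0.05) are independent fields because the headline significance
#' criteria and the bar-graph filters use different cut-offs.
#'
#' @param mnar_width Width of the down-shifted imputation Gaussian, as a
#'   multiple of the per-sample standard deviation. Unitless, > 0.
#' @param mnar_shift Left shift of the imputation Gaussian below the
#'   per-sample mean, in per-sample standard deviations. Unitless, > 0.
#' @param n_cycles Number of stochastic imputation cycles (>= 1).
#' @param lfc_min Minimum absolute log2 fold change for significance.
#' @param q_max Maximum Benjamini-Hochberg adjusted p-value for significance.
#' @param count_lfc_cut Absolute log2 fold change cut used by
#'   [count_by_thresholds()] and volcano categories (strict inequality).
#' @param count_p_cut Raw p-value cut used by [count_by_thresholds()] and
#'   volcano categories (strict inequality).
#' @param whisker_mult Boxplot whisker reach as a multiple of the IQR.
#' @param sig_mode `"dual_threshold"` (default) calls significance when both
#'   `|lfc| >= lfc_min` and `q <= q_max`; `"curve"` lets the effective
#'   adjusted-p threshold rise from 0 at `|lfc| = lfc_min` toward `q_max`
#'   asymptotically (see [significance_call()]).
#' @param curve_steepness Positive steepness of the curve-mode threshold.
#' @param contaminant_prefixes Protein-id prefixes marking contaminant or
#'   decoy entries to be removed before analysis.
#' @param seed Integer root seed for all stochastic steps.
#'
#' @return An object of class `analysis_config` (a named list).
#' @examples
#' cfg <- analysis_config(seed = 7)
#' cfg$mnar_shift
#' @export
analysis_config <- function(mnar_width = 0.3,
                            mnar_shift = 2.5,
                            n_cycles = 20L,
                            lfc_min = 1,
                            q_max = 0.05,
                            count_lfc_cut = 0.5,
                            count_p_cut = 0.05,
                            whisker_mult = 1.5,
                            sig_mode = c("dual_threshold", "curve"),
                            curve_steepness = 2,
                            contaminant_prefixes = c("CON__", "REV__"),
                            seed = 1L) {
  sig_mode <- match.arg(sig_mode)
  stopifnot(
    is.numeric(mnar_width), length(mnar_width) == 1L, mnar_width > 0,
    is.numeric(mnar_shift), length(mnar_shift) == 1L, mnar_shift > 0,
    is.numeric(n_cycles), length(n_cycles) == 1L, n_cycles >= 1,
    n_cycles == as.integer(n_cycles),
    is.numeric(lfc_min), lfc_min >= 0,
    is.numeric(q_max), q_max > 0, q_max < 1,
    is.numeric(count_lfc_cut), count_lfc_cut >= 0,
    is.numeric(count_p_cut), count_p_cut > 0, count_p_cut < 1,
    is.numeric(whisker_mult), whisker_mult > 0,
    is.numeric(curve_steepness), curve_steepness > 0,
    is.character(contaminant_prefixes),
    is.numeric(seed), length(seed) == 1L, is.finite(seed)
  )
  structure(list(
    mnar_width = mnar_width,
    mnar_shift = mnar_shift,
    n_cycles = as.integer(n_cycles),
    lfc_min = lfc_min,
    q_max = q_max,
    count_lfc_cut = count_lfc_cut,
    count_p_cut = count_p_cut,
    whisker_mult = whisker_mult,
    sig_mode = sig_mode,
    curve_steepness = curve_steepness,
    contaminant_prefixes = contaminant_prefixes,
    seed = as.integer(seed)
  ), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("LFQ analysis configuration\n")
  cat(sprintf("  imputation : shift %.3g sd, width %.3g sd, %d cycles\n",
              x$mnar_shift, x$mnar_width, x$n_cycles))
  cat(sprintf("  significance (%s): |log2FC| >= %.3g and q <= %.3g\n",
              x$sig_mode, x$lfc_min, x$q_max))
  cat(sprintf("  count filters: |log2FC| > %.3g, p < %.3g\n",
              x$count_lfc_cut, x$count_p_cut))
  cat(sprintf("  contaminant prefixes: %s\n",
              paste(x$contaminant_prefixes, collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
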