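#' Invert the trigamma function
#'
#' Newton iteration for `y` such that `trigamma(y) = x`, used when
#' moment-matching the variance prior. Converges to a relative tolerance
#' of 1e-8.
#' @param x Positive target value(s).
#' @return `y` with `trigamma(y) = x`; `Inf` maps to 0-adjacent, 0 to `Inf`.
#' @keywords internal
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(if (xi > 0) 0 else NA_real_)
    if (xi <= 0) return(Inf)
    # very large/small targets: trigamma(y) ~ 1/y + 1/(2y^2)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (iter in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) < 1e-8 * y) break
    }
    y
  }, numeric(1L))
}

#' Fit the empirical-Bayes variance prior
#'
#' Estimates the scaled inverse chi-square prior of the moderated t-test
#' from the per-protein sample variances. Under the hierarchical model
#' `s_g^2 | sigma_g^2 ~ sigma_g^2 chi^2_d / d`,
#' `1/sigma_g^2 ~ chi^2_d0 / (d0 s0^2)`, the log sample variances follow a
#' log scaled-F distribution; the prior degrees of freedom `d0` and prior
#' variance `s0^2` are obtained by matching the empirical mean and
#' variance of `log s_g^2` to its theoretical digamma/trigamma moments,
#' with the trigamma equation inverted by Newton iteration. When the
#' empirical spread of the log variances does not exceed what sampling
#' noise alone produces, the prior is a point mass: `d0 = Inf` and
#' `s0^2 = mean(s^2)`.
#'
#' @param s2 Per-protein sample variances (pooled residual variances).
#' @param df Residual degrees of freedom, scalar or per-protein vector.
#' @return Object of class `variance_prior`: list with `d0` and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  if (all(s2 <= 0, na.rm = TRUE)) stop("all sample variances are zero")
  df <- rep_len(df, length(s2))
  keep <- is.finite(s2) & s2 > 0 & df > 0
  s2f <- s2[keep]
  dff <- df[keep]
  if (length(s2f) < 2L)
    stop("need >= 2 proteins with positive variance to fit the prior")

  e <- log(s2f) - digamma(dff / 2) + log(dff / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1L) - mean(trigamma(dff / 2))

  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- mean(s2f)
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("variance_prior: d0 = %s, s0^2 = %.6g\n",
              format(x$d0), x$s0_sq))
  invisible(x)
}

#' Moderated two-sample t-test on a completed matrix
#'
#' Per protein: the pooled two-group variance `s_g^2` with
#' `d_g = n1 + n2 - 2` degrees of freedom is shrunk toward the prior,
#' `s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and the statistic
#' `t = (mean2 - mean1) / sqrt(s_tilde^2 (1/n1 + 1/n2))` is referred to a
#' t distribution with `d0 + d_g` degrees of freedom (standard normal when
#' `d0` is unbounded). The log2 fold change is the second condition minus
#' the first, conditions ordered by first appearance in the design.
#' Setting `prior = list(d0 = 0, ...)` recovers the ordinary pooled
#' two-sample t-test.
#'
#' @param values Complete numeric matrix (proteins x samples), e.g. one
#'   cycle from [run_cycles()].
#' @param design Named character vector (sample -> condition), exactly two
#'   conditions with >= 2 replicates each.
#' @param prior A `variance_prior`; fitted from this matrix when `NULL`.
#' @return Object of class `cycle_de_result`: data frame with columns
#'   `protein`, `lfc`, `s2`, `df`, `s2_post`, `t`, `p`, `q`.
#' @export
moderated_t <- function(values, design, prior = NULL) {
  if (anyNA(values))
    stop("moderated_t needs a complete matrix; impute first")
  design <- design[colnames(values)]
  if (anyNA(names(design)))
    stop("design does not cover all samples")
  conds <- unique(unname(design))
  if (length(conds) != 2L)
    stop("moderated_t needs exactly 2 conditions, found ", length(conds))
  i1 <- which(unname(design) == conds[1L])
  i2 <- which(unname(design) == conds[2L])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L)
    stop("each condition needs >= 2 replicates")

  m1 <- rowMeans(values[, i1, drop = FALSE])
  m2 <- rowMeans(values[, i2, drop = FALSE])
  ss1 <- rowSums((values[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((values[, i2, drop = FALSE] - m2)^2)
  dg <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / dg
  lfc <- m2 - m1

  if (is.null(prior)) prior <- fit_variance_prior(s2, dg)
  d0 <- prior$d0
  s2_post <- if (is.infinite(d0)) {
    rep(prior$s0_sq, length(s2))
  } else {
    (d0 * prior$s0_sq + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- if (is.infinite(d0)) {
    2 * stats::pnorm(-abs(t))
  } else {
    2 * stats::pt(-abs(t), df = d0 + dg)
  }
  p <- pmin(1, pmax(p, .Machine$double.xmin))
  out <- data.frame(
    protein = rownames(values), lfc = lfc, s2 = s2, df = dg,
    s2_post = s2_post, t = t, p = p, q = bh_adjust(p),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("cycle_de_result", "data.frame")
  attr(out, "conditions") <- conds
  attr(out, "prior") <- prior
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: sort p ascending, take
#' `q_(i) = min_{j >= i} p_(j) * n / j` capped at 1, restore input order.
#' Delegates to [stats::p.adjust()] after validating the input range.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (q-values), same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Combined fold-change / adjusted-p significance call
#'
#' In `dual_threshold` mode (the default criteria): significant iff
#' `|lfc| >= lfc_min` and `q <= q_max`. In `curve` mode the adjusted-p
#' threshold depends on the fold change,
#' `q <= q_max * (1 - 2^(-steepness * (|lfc| - lfc_min)))` for
#' `|lfc| > lfc_min`: it is 0 at the fold-change cut and approaches
#' `q_max` only at asymptotically high fold changes.
#'
#' @param lfc Log2 fold change(s).
#' @param q Adjusted p-value(s).
#' @param config An [analysis_config()].
#' @return Logical vector of calls.
#' @export
significance_call <- function(lfc, q, config = analysis_config()) {
  a <- abs(lfc)
  if (config$sig_mode == "dual_threshold") {
    a >= config$lfc_min & q <= config$q_max
  } else {
    thr <- config$q_max *
      (1 - 2^(-config$curve_steepness * (a - config$lfc_min)))
    a > config$lfc_min & q <= thr
  }
}

#' Aggregate per-cycle results into a final differential-expression table
#'
#' The log2 fold change is averaged over cycles; p and q are summarised by
#' their across-cycle medians (diagnostics); `n_cycles_significant` counts
#' the cycles in which [significance_call()] fires on that cycle's own
#' (lfc, q). The final call requires a strict majority of significant
#' cycles and that the aggregated (lfc, q) themselves pass the criteria,
#' so a flagged protein always satisfies the fold-change threshold on its
#' reported aggregate. Direction is `up`/`down` by the sign of the
#' aggregated fold change for significant proteins, `ns` otherwise.
#'
#' @param cycle_results List of `cycle_de_result` objects over the same
#'   proteins (e.g. [moderated_t()] mapped over [run_cycles()] output).
#' @param config An [analysis_config()].
#' @return Object of class `de_table`: data frame with columns `protein`,
#'   `lfc`, `t`, `p`, `q`, `n_cycles_significant`, `significant`,
#'   `direction`.
#' @export
aggregate_cycles <- function(cycle_results, config = analysis_config()) {
  stopifnot(length(cycle_results) >= 1L)
  prot <- cycle_results[[1L]]$protein
  for (r in cycle_results)
    if (!identical(r$protein, prot))
      stop("cycle results cover different protein sets")
  n_cyc <- length(cycle_results)
  lfc_m <- vapply(cycle_results, `[[`, numeric(length(prot)), "lfc")
  t_m <- vapply(cycle_results, `[[`, numeric(length(prot)), "t")
  p_m <- vapply(cycle_results, `[[`, numeric(length(prot)), "p")
  q_m <- vapply(cycle_results, `[[`, numeric(length(prot)), "q")
  dim(lfc_m) <- dim(t_m) <- dim(p_m) <- dim(q_m) <- c(length(prot), n_cyc)

  sig_m <- significance_call(lfc_m, q_m, config)
  dim(sig_m) <- dim(lfc_m)
  n_sig <- rowSums(sig_m)
  lfc <- rowMeans(lfc_m)
  q <- apply(q_m, 1L, stats::median)
  final <- (n_sig > n_cyc / 2) & significance_call(lfc, q, config)
  out <- data.frame(
    protein = prot,
    lfc = lfc,
    t = apply(t_m, 1L, stats::median),
    p = apply(p_m, 1L, stats::median),
    q = q,
    n_cycles_significant = as.integer(n_sig),
    significant = final,
    direction = ifelse(final, ifelse(lfc > 0, "up", "down"), "ns"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("de_table", "data.frame")
  attr(out, "n_cycles") <- n_cyc
  attr(out, "conditions") <- attr(cycle_results[[1L]], "conditions")
  out
}

#' Count proteins passing the figure-style filters
#'
#' Strict-inequality counts matching the published bar graphs: regulated
#' means `|lfc| > count_lfc_cut` (down if negative, up if positive),
#' significant means raw `p < count_p_cut`, and the combined counts
#' require both.
#'
#' @param table A `de_table` (or any data frame with `lfc` and `p`).
#' @param config An [analysis_config()].
#' @return Named list: `down`, `up`, `significant`, `nonsignificant`,
#'   `down_sig`, `up_sig`.
#' @export
count_by_thresholds <- function(table, config = analysis_config()) {
  lfc <- table$lfc
  p <- table$p
  down <- lfc < -config$count_lfc_cut
  up <- lfc > config$count_lfc_cut
  sig <- p < config$count_p_cut
  list(
    down = sum(down), up = sum(up),
    significant = sum(sig), nonsignificant = sum(!sig),
    down_sig = sum(down & sig), up_sig = sum(up & sig)
  )
}
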