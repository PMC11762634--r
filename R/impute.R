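#' Classify missing cells by replicate-group detection count
#'
#' Implements the detection-conditional rule of the pipeline: within each
#' protein x condition block, if at most one replicate was detected, the
#' missing cells are treated as left-censored (`mnar_rule`) and will be
#' filled from the down-shifted per-sample Gaussian; if two or more
#' replicates were detected, the missing cells are `mle_rule` and filled
#' by stochastic draws from a Gaussian maximum-likelihood fit to the
#' block's observed values. Observed cells are labelled `observed`.
#'
#' @param m An [intensity_matrix()]; every condition needs >= 2 replicates.
#' @return Character matrix, same dimensions as `m$values`, with entries
#'   `"observed"`, `"mnar_rule"`, `"mle_rule"`.
#' @export
classify_missing <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  tab <- table(m$design)
  if (any(tab < 2L))
    stop("each condition needs >= 2 replicates to classify missingness")
  v <- m$values
  labels <- matrix("observed", nrow(v), ncol(v), dimnames = dimnames(v))
  for (cond in unique(unname(m$design))) {
    cols <- which(unname(m$design) == cond)
    obs <- !is.na(v[, cols, drop = FALSE])
    ndet <- rowSums(obs)
    lab <- ifelse(ndet <= 1L, "mnar_rule", "mle_rule")
    block <- labels[, cols, drop = FALSE]
    block[!obs] <- rep(lab, ncol(obs))[!obs]
    labels[, cols] <- block
  }
  labels
}

#' Per-sample summary statistics of observed intensities
#'
#' Column-wise mean and standard deviation (n-1 denominator) over the
#' observed (non-missing) cells of each sample. These anchor the
#' down-shifted imputation Gaussian: with at most one detection in a
#' replicate group there is no protein-level spread to estimate, so the
#' sample's whole observed distribution provides the location and scale.
#'
#' @param m An [intensity_matrix()].
#' @return Data frame with columns `sample`, `n_obs`, `mean`, `sd`.
#' @export
column_stats <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  v <- m$values
  n_obs <- colSums(!is.na(v))
  low <- which(n_obs < 2L)
  if (length(low))
    stop("sample '", colnames(v)[low[1L]], "' has fewer than 2 observed values")
  data.frame(
    sample = colnames(v),
    n_obs = n_obs,
    mean = colMeans(v, na.rm = TRUE),
    sd = apply(v, 2L, stats::sd, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Draw down-shifted Gaussian (left-censored) imputation values
#'
#' Draws from `Normal(mean - mnar_shift * sd, (mnar_width * sd)^2)`: a
#' narrow Gaussian centred below the sample's observed distribution, the
#' standard stand-in for intensities that fell under the detection limit.
#' With `sd = 0` the distribution degenerates to the point `mean`.
#'
#' @param n Number of draws.
#' @param col_mean,col_sd Observed mean and sd of the target sample
#'   (one row of [column_stats()]).
#' @param config An [analysis_config()] supplying `mnar_shift` (default
#'   2.5) and `mnar_width` (default 0.3).
#' @return Numeric vector of `n` draws.
#' @export
draw_mnar <- function(n, col_mean, col_sd, config = analysis_config()) {
  stopifnot(col_sd >= 0)
  stats::rnorm(n, col_mean - config$mnar_shift * col_sd,
               config$mnar_width * col_sd)
}

#' Draw Gaussian maximum-likelihood imputation values
#'
#' Fits a Normal distribution to the observed values of a protein x
#' condition block by maximum likelihood (mean = arithmetic mean,
#' variance = n-denominator MLE) and draws from the fit. Stochastic on
#' purpose: repeated imputation cycles must differ to carry imputation
#' uncertainty into the final calls.
#'
#' @param values Observed values of the block (length >= 2).
#' @param n Number of draws.
#' @return Numeric vector of `n` draws.
#' @export
draw_mle <- function(values, n = 1L) {
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    stop("MLE imputation needs >= 2 observed values in the block")
  mu <- mean(values)
  sd_mle <- sqrt(mean((values - mu)^2))
  stats::rnorm(n, mu, sd_mle)
}

# Per-missing-cell imputation location and scale, in protein-major order.
# mnar cells take the column's down-shifted mean and narrow width; mle
# cells take their block's MLE fit. These do not change across cycles.
impute_cell_params <- function(m, labels, stats, config) {
  v <- m$values
  miss <- which(is.na(v))
  ai <- arrayInd(miss, dim(v))
  ord <- order(ai[, 1L], ai[, 2L])
  miss <- miss[ord]
  ai <- ai[ord, , drop = FALSE]
  lab <- labels[miss]

  mu <- sd <- numeric(length(miss))
  cm <- stats$mean[ai[, 2L]]
  cs <- stats$sd[ai[, 2L]]
  is_mnar <- lab == "mnar_rule"
  mu[is_mnar] <- cm[is_mnar] - config$mnar_shift * cs[is_mnar]
  sd[is_mnar] <- config$mnar_width * cs[is_mnar]

  if (any(!is_mnar)) {
    cond_of <- unname(m$design)
    for (cond in unique(cond_of)) {
      cols <- which(cond_of == cond)
      sub <- v[, cols, drop = FALSE]
      nobs <- rowSums(!is.na(sub))
      s <- rowSums(sub, na.rm = TRUE)
      bm <- s / nobs
      ss <- rowSums(sub^2, na.rm = TRUE)
      bv <- pmax(0, ss / nobs - bm^2)
      sel <- !is_mnar & cond_of[ai[, 2L]] == cond
      mu[sel] <- bm[ai[sel, 1L]]
      sd[sel] <- sqrt(bv[ai[sel, 1L]])
    }
  }
  list(idx = miss, mu = mu, sd = sd)
}

#' Run repeated stochastic imputation cycles
#'
#' Produces `config$n_cycles` completed matrices. Each cycle fills every
#' missing cell with one stochastic draw — down-shifted Gaussian for
#' `mnar_rule` cells, block MLE Gaussian for `mle_rule` cells — and never
#' touches an observed cell. Cycle seeds are derived deterministically
#' from `config$seed`, and within a cycle draws are made for missing cells
#' in protein-major order, so results are bit-reproducible and do not
#' depend on how cells are traversed.
#'
#' @param m An [intensity_matrix()].
#' @param labels Output of [classify_missing()]; computed if `NULL`.
#' @param stats Output of [column_stats()]; computed if `NULL`.
#' @param config An [analysis_config()].
#' @return Object of class `imputed_cycles`: list with `cycles` (list of
#'   completed numeric matrices), `labels`, `design` and `seed`.
#' @export
run_cycles <- function(m, labels = NULL, stats = NULL,
                       config = analysis_config()) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (is.null(labels)) labels <- classify_missing(m)
  if (is.null(stats)) stats <- column_stats(m)
  par <- impute_cell_params(m, labels, stats, config)

  set.seed(config$seed)
  cycle_seeds <- sample.int(2147483646L, config$n_cycles)

  cycles <- vector("list", config$n_cycles)
  for (k in seq_len(config$n_cycles)) {
    filled <- m$values
    if (length(par$idx)) {
      set.seed(cycle_seeds[k])
      filled[par$idx] <- par$mu + par$sd * stats::rnorm(length(par$idx))
    }
    cycles[[k]] <- filled
  }
  structure(list(cycles = cycles, labels = labels, design = m$design,
                 seed = config$seed),
            class = "imputed_cycles")
}

#' @export
print.imputed_cycles <- function(x, ...) {
  cat(sprintf("imputed_cycles: %d cycle(s), %d x %d matrix, %d imputed cells\n",
              length(x$cycles), nrow(x$cycles[[1L]]), ncol(x$cycles[[1L]]),
              sum(x$labels != "observed")))
  invisible(x)
}
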