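#' Simulation parameters for synthetic LFQ data
#'
#' Defaults emulate the study design the pipeline was built for: two
#' conditions with three replicates each and roughly 5,500 quantified
#' proteins, on the log2 intensity scale typical of protein-level LFQ
#' exports (grand mean ~20, between-protein spread ~2 log2 units).
#' Missingness combines left censoring — cells drop out with logistic
#' probability rising as the latent intensity falls below
#' `mnar_censor_midpoint` — and a small completely-at-random component.
#'
#' @param n_proteins Number of simulated proteins.
#' @param n_replicates Replicates per condition (>= 2).
#' @param de_fraction Proportion of proteins with a true effect.
#' @param effect_size_mean,effect_size_sd Mean and sd of the absolute log2
#'   effect size; magnitudes are truncated below at 0.2 so every "true"
#'   effect is non-zero, and signs alternate so both directions occur.
#' @param baseline_mean,baseline_sd Grand mean and between-protein sd of
#'   the per-protein baseline log2 intensity.
#' @param replicate_sd Within-group (technical + biological) sd, log2 units.
#' @param mnar_censor_midpoint Latent log2 intensity at which the censoring
#'   probability is 0.5.
#' @param mnar_censor_scale Logistic scale of the censoring curve (log2
#'   units); smaller is closer to a hard detection limit.
#' @param mcar_rate Completely-at-random missingness rate applied on top.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_proteins = 5500L,
                              n_replicates = 3L,
                              de_fraction = 0.05,
                              effect_size_mean = 1.5,
                              effect_size_sd = 0.5,
                              baseline_mean = 20,
                              baseline_sd = 2,
                              replicate_sd = 0.5,
                              mnar_censor_midpoint = 17,
                              mnar_censor_scale = 0.8,
                              mcar_rate = 0.02,
                              seed = 1L) {
  stopifnot(
    n_proteins >= 1, n_replicates >= 2,
    de_fraction >= 0, de_fraction <= 1,
    effect_size_sd > 0, baseline_sd > 0, replicate_sd > 0,
    mnar_censor_scale >= 0, mcar_rate >= 0, mcar_rate <= 1,
    is.numeric(seed), length(seed) == 1L, is.finite(seed)
  )
  structure(list(
    n_proteins = as.integer(n_proteins),
    n_replicates = as.integer(n_replicates),
    de_fraction = de_fraction,
    effect_size_mean = effect_size_mean,
    effect_size_sd = effect_size_sd,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    replicate_sd = replicate_sd,
    mnar_censor_midpoint = mnar_censor_midpoint,
    mnar_censor_scale = mnar_censor_scale,
    mcar_rate = mcar_rate,
    seed = as.integer(seed)
  ), class = "simulation_params")
}

#' Generate a synthetic LFQ dataset with known truth
#'
#' Per protein g: baseline `mu_g ~ N(baseline_mean, baseline_sd^2)`; a
#' `de_fraction` subset gets a signed effect `delta_g` (alternating signs)
#' added to the second condition's mean. Each cell is
#' `N(group mean, replicate_sd^2)`, then censored (set missing) with
#' probability `plogis((midpoint - value)/scale)` and additionally dropped
#' completely at random at `mcar_rate`. Conditions are labelled `ctrl` and
#' `trt`; the effect applies to `trt`, so downstream log2 fold changes
#' (second condition minus first) estimate `delta_g` directly.
#'
#' @param params A [simulation_params()] object.
#' @return A list with `matrix` (an [intensity_matrix()]) and `truth`, a
#'   list holding `proteins` (data frame: `protein`, `is_de`, `delta`,
#'   `baseline`), `mechanism` (character matrix: `"none"`, `"censored"`,
#'   `"mcar"`) and `latent` (the complete pre-censoring value matrix).
#' @examples
#' d <- generate_dataset(simulation_params(n_proteins = 50, seed = 3))
#' table(d$truth$proteins$is_de)
#' @export
generate_dataset <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  G <- params$n_proteins
  R <- params$n_replicates
  pid <- sprintf("P%05d", seq_len(G))
  sid <- c(paste0("ctrl_", seq_len(R)), paste0("trt_", seq_len(R)))
  design <- stats::setNames(rep(c("ctrl", "trt"), each = R), sid)

  baseline <- stats::rnorm(G, params$baseline_mean, params$baseline_sd)
  n_de <- round(params$de_fraction * G)
  if (params$de_fraction > 0 && n_de < 1)
    warning("de_fraction too small for n_proteins; zero DE proteins")
  is_de <- rep(FALSE, G)
  delta <- rep(0, G)
  if (n_de >= 1) {
    idx <- sample.int(G, n_de)
    is_de[idx] <- TRUE
    mag <- pmax(0.2, stats::rnorm(n_de, params$effect_size_mean,
                                  params$effect_size_sd))
    sgn <- rep(c(1, -1), length.out = n_de)
    delta[idx] <- sgn * mag
  }

  mu <- cbind(matrix(baseline, G, R),
              matrix(baseline + delta, G, R))
  latent <- mu + stats::rnorm(G * 2L * R, 0, params$replicate_sd)
  dimnames(latent) <- list(pid, sid)

  p_cens <- if (params$mnar_censor_scale > 0) {
    stats::plogis((params$mnar_censor_midpoint - latent) /
                    params$mnar_censor_scale)
  } else {
    (latent < params$mnar_censor_midpoint) * 1
  }
  censored <- matrix(stats::runif(length(latent)) < p_cens, G,
                     dimnames = dimnames(latent))
  mcar <- matrix(stats::runif(length(latent)) < params$mcar_rate, G,
                 dimnames = dimnames(latent)) & !censored

  mechanism <- matrix("none", G, 2L * R, dimnames = dimnames(latent))
  mechanism[censored] <- "censored"
  mechanism[mcar] <- "mcar"

  values <- latent
  values[mechanism != "none"] <- NA_real_

  list(
    matrix = intensity_matrix(values, design),
    truth = list(
      proteins = data.frame(protein = pid, is_de = is_de, delta = delta,
                            baseline = baseline, stringsAsFactors = FALSE),
      mechanism = mechanism,
      latent = latent
    )
  )
}

#' Write a simulated dataset to disk
#'
#' Side-car writer for [generate_dataset()]: intensity TSV, design TSV and
#' per-protein truth TSV under a common file prefix.
#' @param dataset The list returned by [generate_dataset()].
#' @param prefix Path prefix; files `<prefix>_intensity.tsv`,
#'   `<prefix>_design.tsv`, `<prefix>_truth.tsv` are written.
#' @return Character vector of the three paths, invisibly.
#' @export
write_dataset <- function(dataset, prefix) {
  paths <- paste0(prefix, c("_intensity.tsv", "_design.tsv", "_truth.tsv"))
  write_intensity_table(dataset$matrix, paths[1L])
  write_design(dataset$matrix, paths[2L])
  utils::write.table(dataset$truth$proteins, paths[3L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Confusion counts of significance calls against simulated truth
#'
#' @param de_table A `de_table` data frame from [aggregate_cycles()] (or
#'   any data frame with `protein` and logical `significant` columns).
#' @param truth The `truth` element of [generate_dataset()] output (or its
#'   `proteins` data frame).
#' @return Named list: `tp`, `fp`, `tn`, `fn`, `fdp` (false-discovery
#'   proportion, `fp / max(1, fp + tp)`) and `sensitivity`
#'   (`tp / max(1, tp + fn)`).
#' @export
truth_confusion <- function(de_table, truth) {
  tr <- if (is.data.frame(truth)) truth else truth$proteins
  if (!setequal(de_table$protein, tr$protein) ||
      nrow(de_table) != nrow(tr))
    stop("protein ids of calls and truth do not match")
  is_de <- tr$is_de[match(de_table$protein, tr$protein)]
  called <- de_table$significant
  tp <- sum(called & is_de)
  fp <- sum(called & !is_de)
  tn <- sum(!called & !is_de)
  fn <- sum(!called & is_de)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       fdp = fp / max(1L, fp + tp),
       sensitivity = tp / max(1L, tp + fn))
}
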