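#' Run the full differential-expression pipeline
#'
#' Chains the stages end to end: contaminant filtering, detection-
#' conditional missingness classification, repeated stochastic imputation
#' cycles, a moderated t-test with Benjamini-Hochberg adjustment per
#' cycle, cross-cycle aggregation into final significance calls,
#' threshold counts, PCA and sample/protein clustering on the across-cycle
#' mean matrix, a volcano table, and (when gene sets are given) Fisher
#' over-representation of the significant proteins. When `out_dir` is
#' given, every table is written as TSV together with a JSON run manifest
#' recording the configuration, seed, input digests, output digests and
#' package version; re-running with the same inputs and seed reproduces
#' all outputs bit-identically.
#'
#' @param m An [intensity_matrix()], or a path to an intensity TSV (then
#'   `design` must be supplied).
#' @param config An [analysis_config()].
#' @param design Optional design (used only when `m` is a path).
#' @param sets Optional `gene_set_collection` (or GMT path) for
#'   enrichment of the significant calls.
#' @param regulons Optional signed regulon list (or TSV path) for
#'   activation z-scores.
#' @param out_dir Optional output directory; created if absent.
#' @return Object of class `lfq_run`: list with `de_table`, `counts`,
#'   `cycles`, `mean_matrix`, `pca`, `sample_clust`, `protein_clust`,
#'   `volcano`, `enrichment` (or `NULL`), `config` and `manifest`.
#' @export
run_pipeline <- function(m, config = analysis_config(), design = NULL,
                         sets = NULL, regulons = NULL, out_dir = NULL) {
  input_path <- NULL
  if (is.character(m)) {
    input_path <- m
    m <- read_intensity_table(m, design)
  }
  stopifnot(inherits(m, "intensity_matrix"))
  conds <- validate_for_de(m)
  message("log2 fold change orientation: ", conds[2L], " - ", conds[1L])

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  filtered <- stage("filter", filter_contaminants(m, config))
  labels <- stage("classify", classify_missing(filtered))
  imp <- stage("impute", run_cycles(filtered, labels, config = config))
  cycle_results <- stage("detest", lapply(imp$cycles, moderated_t,
                                          design = filtered$design))
  de <- stage("aggregate", aggregate_cycles(cycle_results, config))
  counts <- count_by_thresholds(de, config)

  mean_matrix <- Reduce(`+`, imp$cycles) / length(imp$cycles)
  message("multivariate input: across-cycle mean matrix")
  pca <- stage("pca", lfq_pca(mean_matrix))
  sample_clust <- stage("cluster", cluster_intensity(mean_matrix, "columns"))
  protein_clust <- if (nrow(mean_matrix) >= 3L) {
    ok <- apply(mean_matrix, 1L, stats::var) > 0
    stage("cluster", cluster_intensity(mean_matrix[ok, , drop = FALSE],
                                       "rows"))
  }
  volcano <- stage("report", volcano_table(de, config))

  enrichment <- NULL
  if (!is.null(sets)) {
    if (is.character(sets)) sets <- read_gmt(sets)
    if (is.character(regulons)) regulons <- read_regulons(regulons)
    enrichment <- stage("enrich", enrich_de(de, sets, regulons))
  }

  res <- structure(list(
    de_table = de, counts = counts, cycles = imp,
    mean_matrix = mean_matrix, pca = pca,
    sample_clust = sample_clust, protein_clust = protein_clust,
    volcano = volcano, enrichment = enrichment,
    config = config, manifest = NULL
  ), class = "lfq_run")

  if (!is.null(out_dir)) {
    res$manifest <- write_run(res, out_dir, input_path)
  }
  res
}

write_run <- function(res, out_dir, input_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  tsv <- function(df, f) {
    utils::write.table(df, fp(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  }
  outs <- c(
    tsv(res$de_table, "de_table.tsv"),
    tsv(data.frame(filter = names(res$counts),
                   count = unlist(res$counts)), "counts.tsv"),
    tsv(data.frame(sample = rownames(res$pca$scores), res$pca$scores,
                   check.names = FALSE), "pca_scores.tsv"),
    tsv(data.frame(component = seq_along(res$pca$variance_explained),
                   proportion = res$pca$variance_explained),
        "pca_variance.tsv"),
    tsv(res$volcano, "volcano.tsv"),
    tsv(data.frame(res$sample_clust$merge,
                   height = res$sample_clust$height),
        "sample_clust_merges.tsv")
  )
  if (!is.null(res$enrichment)) outs <- c(outs, tsv(res$enrichment,
                                                    "enrichment.tsv"))
  manifest <- list(
    tool = paste0("lfqde ", as.character(utils::packageVersion("lfqde"))),
    seed = res$config$seed,
    config = unclass(res$config),
    conditions = attr(res$de_table, "conditions"),
    input = if (!is.null(input_path))
      list(path = input_path,
           md5 = unname(tools::md5sum(input_path))),
    outputs = lapply(stats::setNames(outs, outs), function(f)
      unname(tools::md5sum(file.path(out_dir, f))))
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  manifest
}

#' @export
print.lfq_run <- function(x, ...) {
  cat("LFQ differential-expression run\n")
  cat(sprintf("  proteins tested: %d over %d cycle(s)\n",
              nrow(x$de_table), attr(x$de_table, "n_cycles")))
  cat(sprintf("  significant: %d (|log2FC| >= %.3g, q <= %.3g, majority of cycles)\n",
              sum(x$de_table$significant), x$config$lfc_min, x$config$q_max))
  with(x$counts, cat(sprintf(
    "  count filters: %d down / %d up (|lfc| > %.2g); %d at p < %.2g; %d/%d at both\n",
    down, up, x$config$count_lfc_cut, significant, x$config$count_p_cut,
    down_sig, up_sig)))
  cat(sprintf("  PC1 %.0f%%, PC2 %.0f%% of variance\n",
              100 * x$pca$variance_explained[1L],
              100 * x$pca$variance_explained[2L]))
  invisible(x)
}
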