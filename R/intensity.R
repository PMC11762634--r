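#' Protein intensity matrix with sample design
#'
#' The central container of the pipeline: a proteins x samples matrix of
#' log2 intensities in which any cell may be `NA` (not quantified), plus a
#' mapping of each sample to its experimental condition (replicate group).
#'
#' @param values Numeric matrix, rows = proteins (unique rownames),
#'   columns = samples (unique colnames). `NA` marks missing cells.
#' @param design Named character vector mapping each sample id to its
#'   condition label, or a two-column data frame (`sample`, `condition`).
#' @param is_log2 Logical; whether `values` are already on the log2 scale.
#'   Raw positive intensities are log2-transformed here so that all
#'   downstream arithmetic is on log2 scale.
#'
#' @return An object of class `intensity_matrix`: a list with elements
#'   `values` (log2 matrix), `design` (named character vector) and
#'   `is_log2` (`TRUE`, recording that storage is log2).
#' @examples
#' v <- matrix(rnorm(12, 20), 3, 4,
#'             dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
#' m <- intensity_matrix(v, c(S1 = "a", S2 = "a", S3 = "b", S4 = "b"))
#' n_missing(m)
#' @export
intensity_matrix <- function(values, design, is_log2 = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) || is.null(sid))
    stop("`values` must have rownames (protein ids) and colnames (sample ids)")
  if (anyDuplicated(pid))
    stop("duplicate protein id: ", pid[duplicated(pid)][1L])
  if (anyDuplicated(sid))
    stop("duplicate sample id: ", sid[duplicated(sid)][1L])
  design <- as_design(design)
  absent <- setdiff(sid, names(design))
  if (length(absent))
    stop("sample(s) without a condition in the design: ",
         paste(absent, collapse = ", "))
  design <- design[sid]
  if (!isTRUE(is_log2)) {
    neg <- which(values < 0)
    if (length(neg))
      stop("raw intensities must be non-negative; found negative value at ",
           "cell [", arr_cell(values, neg[1L]), "]")
    values[values == 0] <- NA_real_
    values <- log2(values)
  }
  structure(list(values = values, design = design, is_log2 = TRUE),
            class = "intensity_matrix")
}

as_design <- function(design) {
  if (is.data.frame(design)) {
    if (ncol(design) < 2L)
      stop("design data frame needs columns sample and condition")
    out <- as.character(design[[2L]])
    names(out) <- as.character(design[[1L]])
    design <- out
  }
  if (is.null(names(design)) || !is.character(design))
    stop("`design` must be a named character vector (sample -> condition)")
  if (anyDuplicated(names(design)))
    stop("duplicate sample id in design: ",
         names(design)[duplicated(names(design))][1L])
  design
}

arr_cell <- function(m, idx) {
  ai <- arrayInd(idx, dim(m))
  paste0(rownames(m)[ai[1L]], ", ", colnames(m)[ai[2L]])
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d proteins x %d samples (log2)\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$design)
  cat("  conditions:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat(sprintf("  missing cells: %d (%.1f%%)\n", n_missing(x),
              100 * n_missing(x) / length(x$values)))
  invisible(x)
}

#' Number of missing cells in an intensity matrix
#' @param m An `intensity_matrix`.
#' @return Integer count of `NA` cells.
#' @export
n_missing <- function(m) sum(is.na(m$values))

#' Check that a matrix supports two-group differential testing
#'
#' Errors unless the design has exactly two conditions with at least two
#' replicates each.
#' @param m An `intensity_matrix`.
#' @return Invisibly, the condition labels in order of first appearance in
#'   the design; the second condition is the log2-fold-change numerator.
#' @export
validate_for_de <- function(m) {
  conds <- unique(unname(m$design))
  if (length(conds) != 2L)
    stop("differential testing needs exactly 2 conditions, found ",
         length(conds))
  tab <- table(m$design)
  if (any(tab < 2L))
    stop("each condition needs >= 2 replicates; condition '",
         names(tab)[which.min(tab)], "' has ", min(tab))
  invisible(conds)
}

#' Read a protein intensity table
#'
#' Reads a delimited text export (first column protein id, one numeric
#' column per sample). Empty cells and `NA` denote missing values; zero raw
#' intensities are treated as not-quantified by default, matching LFQ
#' export conventions.
#'
#' @param path Path to a TSV (default) or CSV file; `.csv` extension
#'   switches the separator.
#' @param design Sample-to-condition mapping (named character vector, data
#'   frame, or path to a two-column TSV read with [read_design()]).
#' @param is_log2 Whether the stored values are already log2; raw values
#'   are log2-transformed on read.
#' @param zero_as_missing Treat zeros as missing (default `TRUE`).
#' @return An [intensity_matrix()].
#' @export
read_intensity_table <- function(path, design, is_log2 = TRUE,
                                 zero_as_missing = TRUE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "", na.strings = NULL)
  if (ncol(raw) < 2L) stop("intensity table needs an id column plus samples")
  pid <- raw[[1L]]
  dup <- pid[duplicated(pid)]
  if (length(dup)) stop("duplicate protein id: ", dup[1L])
  sid <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow(raw), length(sid),
                 dimnames = list(pid, sid))
  for (j in seq_along(sid)) {
    cell <- trimws(raw[[j + 1L]])
    empty <- cell == "" | toupper(cell) == "NA" | cell == "NaN"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(num))
    if (length(bad))
      stop("non-numeric value '", cell[bad[1L]], "' at row ", bad[1L],
           " (", pid[bad[1L]], "), column '", sid[j], "'")
    num[empty] <- NA_real_
    vals[, j] <- num
  }
  if (zero_as_missing) vals[!is.na(vals) & vals == 0] <- NA_real_
  if (is.character(design) && length(design) == 1L && file.exists(design))
    design <- read_design(design)
  intensity_matrix(vals, design, is_log2 = is_log2)
}

#' Write a protein intensity table
#'
#' Inverse of [read_intensity_table()]: tab-separated, 17 significant
#' digits so that a write/read round trip reproduces values bit-exactly,
#' missing cells written as `NA`.
#' @param m An `intensity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(m, path) {
  v <- m$values
  chr <- matrix(sprintf("%.17g", v), nrow(v), dimnames = dimnames(v))
  chr[is.na(v)] <- "NA"
  df <- data.frame(protein = rownames(v), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' Two-column tab-separated file: sample id, condition label. A header row
#' is detected by the literal column names `sample` and `condition`.
#' @param path Path to the TSV.
#' @return Named character vector mapping sample id to condition.
#' @export
read_design <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("design file needs two columns (sample, condition)")
  if (tolower(df[1L, 1L]) == "sample") df <- df[-1L, , drop = FALSE]
  as_design(stats::setNames(df[[2L]], df[[1L]]))
}

#' Write a sample design table
#' @param design Named character vector (sample -> condition) or an
#'   `intensity_matrix` whose design should be written.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  if (inherits(design, "intensity_matrix")) design <- design$design
  utils::write.table(
    data.frame(sample = names(design), condition = unname(design)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove contaminant and decoy entries
#'
#' Drops rows whose protein id starts with any configured contaminant
#' prefix (defaults `CON__` and `REV__`, the common search-engine markers).
#' Idempotent; matching zero rows is allowed.
#'
#' @param m An `intensity_matrix`.
#' @param config An [analysis_config()] supplying `contaminant_prefixes`.
#' @return The filtered `intensity_matrix`; the number of removed rows is
#'   reported via [message()] and attached as attribute `n_removed`.
#' @export
filter_contaminants <- function(m, config = analysis_config()) {
  stopifnot(inherits(m, "intensity_matrix"))
  prefixes <- config$contaminant_prefixes
  hit <- rep(FALSE, nrow(m$values))
  for (p in prefixes)
    hit <- hit | startsWith(rownames(m$values), p)
  out <- m
  out$values <- m$values[!hit, , drop = FALSE]
  message(sum(hit), " contaminant row(s) removed")
  if (all(hit) && length(hit)) warning("all rows matched contaminant prefixes")
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Read a GMT gene-set file
#'
#' Standard GMT layout: one set per line, `name TAB description TAB
#' member...`. Duplicate members within a set are dropped.
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of unique
#'   member vectors) and `description` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descr <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT line ", i, " has an empty member list")
    sets[[f[1L]]] <- members
    descr[f[1L]] <- f[2L]
  }
  structure(list(sets = sets, description = descr),
            class = "gene_set_collection")
}

#' Read a signed regulon table
#'
#' Three-column TSV (`set`, `member`, `direction`) with direction +1 or -1:
#' the expected regulation sign of each member under set activation. Used
#' by [activation_z()].
#' @param path Path to the TSV (header optional, detected by the literal
#'   first field `set`).
#' @return Named list of named numeric vectors (member -> expected sign).
#' @export
read_regulons <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "")
  if (ncol(df) < 3L) stop("regulon file needs columns set, member, direction")
  if (tolower(df[1L, 1L]) == "set") df <- df[-1L, , drop = FALSE]
  dir <- as.numeric(df[[3L]])
  if (any(!dir %in% c(-1, 1)))
    stop("regulon directions must be +1 or -1")
  split(stats::setNames(dir, df[[2L]]), df[[1L]])
}
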