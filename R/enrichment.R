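#' Fisher exact over-representation of gene sets
#'
#' For each set, tests whether its overlap with the query (e.g. the
#' significant proteins) exceeds chance given the universe of quantified
#' proteins: one-sided hypergeometric upper-tail p,
#' `p = sum_{j >= k} C(m, j) C(N - m, n - j) / C(N, n)`, with
#' Benjamini-Hochberg adjustment across sets. Sets are intersected with
#' the universe before testing; the universe should be all quantified
#' proteins after contaminant filtering, i.e. the tested population.
#'
#' @param query Character vector of query identifiers (must lie in
#'   `universe`).
#' @param sets A `gene_set_collection` from [read_gmt()], or a named list
#'   of member vectors.
#' @param universe Character vector of all eligible identifiers.
#' @param alternative `"over"` (one-sided over-representation, default)
#'   or `"two.sided"` (via [stats::fisher.test()]).
#' @return Data frame with one row per set: `set`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `q`.
#' @export
fisher_enrichment <- function(query, sets, universe,
                              alternative = c("over", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  out_q <- setdiff(query, universe)
  if (length(out_q))
    stop("query id(s) outside the universe: ",
         paste(utils::head(out_q, 3L), collapse = ", "))
  set_list <- if (inherits(sets, "gene_set_collection")) sets$sets else sets
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(set_list), function(nm) {
    members <- intersect(unique(set_list[[nm]]), universe)
    m <- length(members)
    k <- length(intersect(members, query))
    p <- if (alternative == "over") {
      stats::phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
    } else {
      tab <- matrix(c(k, m - k, n - k, N - m - n + k), 2L)
      stats::fisher.test(tab)$p.value
    }
    data.frame(set = nm, overlap = k, set_size = m, query_size = n,
               universe_size = N, p = min(1, p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Signed activation z-score
#'
#' Sign-agreement statistic comparing observed regulation directions with
#' a regulon's expected directions: over the members carrying both an
#' observed and an expected sign, `z = (n_agree - n_disagree) /
#' sqrt(n_agree + n_disagree)`. Positive z: the set behaves as if
#' activated; negative: inhibited. Antisymmetric under flipping all
#' expected signs.
#'
#' @param observed Named numeric vector of observed directions (+1 / -1),
#'   e.g. `sign(lfc)` of the significant proteins.
#' @param expected Named numeric vector of expected directions (+1 / -1)
#'   for the set's members (one element of [read_regulons()]).
#' @return The z-score, or `NA_real_` when no member carries both signs.
#' @examples
#' activation_z(c(A = 1, B = 1, C = -1), c(A = 1, B = 1, C = 1))
#' @export
activation_z <- function(observed, expected) {
  common <- intersect(names(observed), names(expected))
  common <- common[observed[common] != 0]
  if (!length(common)) return(NA_real_)
  agree <- sum(observed[common] == expected[common])
  disagree <- length(common) - agree
  (agree - disagree) / sqrt(agree + disagree)
}

#' Enrichment of significant calls with optional activation z-scores
#'
#' Convenience wrapper: queries are the significant proteins of a
#' `de_table`, the universe is all its proteins, and when signed regulons
#' are supplied each set also gets an activation z from the observed
#' fold-change signs.
#'
#' @param de_table A `de_table` from [aggregate_cycles()].
#' @param sets A `gene_set_collection` or named list.
#' @param regulons Optional named list of signed member vectors
#'   ([read_regulons()]).
#' @return The [fisher_enrichment()] data frame, with a `z` column when
#'   regulons are given.
#' @export
enrich_de <- function(de_table, sets, regulons = NULL) {
  query <- de_table$protein[de_table$significant]
  res <- fisher_enrichment(query, sets, de_table$protein)
  if (!is.null(regulons)) {
    obs <- stats::setNames(sign(de_table$lfc), de_table$protein)
    obs <- obs[de_table$significant]
    res$z <- vapply(res$set, function(nm) {
      if (is.null(regulons[[nm]])) NA_real_
      else activation_z(obs, regulons[[nm]])
    }, numeric(1L))
  }
  res
}
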