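# Independent brute-force oracles used to check the package's fast paths.
# Deliberately naive implementations that share no code with R/.

# Benjamini-Hochberg by its definition: q_i is the smallest FDR level at
# which p_i would be rejected by the step-up rule. O(n^2).
oracle_bh <- function(p) {
  n <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(vapply(cand, function(t) n * t / sum(p <= t), numeric(1))))
  }, numeric(1))
}

# Upper-tail hypergeometric probability by direct enumeration over the
# overlap support.
oracle_hyper_tail <- function(k, m, N, n) {
  js <- max(k, 0):min(m, n)
  if (k > min(m, n)) return(0)
  sum(choose(m, js) * choose(N - m, n - js)) / choose(N, n)
}

# Naive O(n^3) unweighted average-linkage (UPGMA) agglomeration,
# returning the cophenetic distance matrix (which fully determines the
# dendrogram under average linkage).
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  dd <- d
  active <- seq_len(n)
  while (length(active) > 1L) {
    best <- c(NA, NA)
    bestd <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a < b && dd[active[a], active[b]] < bestd) {
        bestd <- dd[active[a], active[b]]
        best <- c(active[a], active[b])
      }
    }
    i <- best[1L]; j <- best[2L]
    for (x in clusters[[i]]) for (y in clusters[[j]])
      coph[x, y] <- coph[y, x] <- bestd
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    for (k in active) {
      if (k == i || k == j) next
      dd[i, k] <- dd[k, i] <- (ni * dd[i, k] + nj * dd[j, k]) / (ni + nj)
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    active <- setdiff(active, j)
  }
  coph
}

# Small intensity matrix builder for unit tests: 2 conditions x n_rep.
tiny_matrix <- function(values, n_rep = 3L, conditions = c("a", "b")) {
  stopifnot(ncol(values) == 2L * n_rep)
  sid <- paste0(rep(conditions, each = n_rep), "_", seq_len(n_rep))
  colnames(values) <- sid
  if (is.null(rownames(values)))
    rownames(values) <- paste0("P", seq_len(nrow(values)))
  intensity_matrix(values, setNames(rep(conditions, each = n_rep), sid))
}

# Ordinary pooled two-sample t-test (textbook formulas), the d0 -> 0
# reference for the moderated test.
oracle_pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  t <- (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}
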