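test_that("variance prior recovers simulated hyperparameters", {
  # s^2 drawn from the hierarchical model with d0 = 4, s0^2 = 1, d = 4
  set.seed(101)
  G <- 5000; d0 <- 4; s0 <- 1; d <- 4
  sigma2 <- d0 * s0 / rchisq(G, d0)
  s2 <- sigma2 * rchisq(G, d) / d
  pr <- fit_variance_prior(s2, d)
  expect_lt(abs(pr$d0 - 4) / 4, 0.15)
  expect_lt(abs(pr$s0_sq - 1) / 1, 0.10)
})

test_that("variance prior matches closed-form two-point moment equations", {
  # two proteins with s^2 = {1, e^2}, df = 4: solve the moment equations
  # independently with uniroot on the trigamma relation
  s2 <- c(1, exp(2)); d <- 4
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  y <- uniroot(function(y) trigamma(y) - evar, c(1e-6, 1e6), tol = 1e-12)$root
  d0_want <- 2 * y
  s0_want <- exp(mean(e) + digamma(y) - log(y))

  pr <- fit_variance_prior(s2, d)
  expect_equal(pr$d0, d0_want, tolerance = 1e-7)
  expect_equal(pr$s0_sq, s0_want, tolerance = 1e-7)
})

test_that("equal variances give an unbounded prior equal to the common value", {
  pr <- fit_variance_prior(rep(0.7, 50), 4)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 0.7)
  expect_error(fit_variance_prior(rep(0, 10), 4), "all sample variances are zero")
})

test_that("variance prior and moderated t agree with limma on random data", {
  skip_if_not_installed("limma")
  set.seed(55)
  v <- matrix(rnorm(1200, 20, 1), 200, 6)
  m <- tiny_matrix(v)
  v <- m$values
  res <- moderated_t(v, m$design)
  pr <- attr(res, "prior")

  design_mat <- model.matrix(~ rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(v, design_mat))
  expect_equal(pr$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(pr$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("d0 -> 0 reproduces the ordinary pooled two-sample t-test", {
  set.seed(77)
  v <- matrix(rnorm(600, 20, 1.5), 100, 6)
  m <- tiny_matrix(v)
  v <- m$values
  res <- moderated_t(v, m$design, prior = list(d0 = 0, s0_sq = 1))
  for (i in seq_len(100)) {
    want <- oracle_pooled_t(v[i, 1:3], v[i, 4:6])
    expect_equal(res$t[i], want$t, tolerance = 1e-10)
    expect_equal(res$p[i], want$p, tolerance = 1e-10)
  }
  # and against stats::t.test on a handful of rows
  for (i in 1:5) {
    tt <- t.test(v[i, 4:6], v[i, 1:3], var.equal = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("unbounded prior gives the closed-form z statistic", {
  set.seed(78)
  v <- matrix(rnorm(300, 20, 1), 50, 6)
  m <- tiny_matrix(v)
  v <- m$values
  res <- moderated_t(v, m$design, prior = list(d0 = Inf, s0_sq = 0.8))
  lfc <- unname(rowMeans(v[, 4:6]) - rowMeans(v[, 1:3]))
  z <- lfc / sqrt(0.8 * (2 / 3))
  expect_equal(res$t, z, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
})

test_that("identical group means give t = 0, p = 1", {
  v <- matrix(rnorm(30, 20), 5, 6)
  v[1, 4:6] <- v[1, 1:3]
  m <- tiny_matrix(v)
  v <- m$values
  res <- moderated_t(v, m$design)
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
  expect_true(all(res$q >= res$p))
})

test_that("BH adjustment matches hand computation and the brute-force oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(91)
  for (i in 1:1000) {
    p <- runif(sample(1:25, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("BH is monotone: raising one p never lowers any q", {
  set.seed(92)
  for (i in 1:50) {
    p <- runif(20)
    j <- sample(20, 1)
    p2 <- p
    p2[j] <- min(1, p[j] + runif(1) * (1 - p[j]))
    expect_true(all(bh_adjust(p2) >= bh_adjust(p) - 1e-12))
  }
})

test_that("significance calls honour both threshold modes", {
  cfg <- analysis_config()
  # the pipeline's flagship case: lfc 2.348 at q 0.01 is significant
  expect_true(significance_call(2.348, 0.01, cfg))
  expect_false(significance_call(0.5, 0.001, cfg))   # under the lfc floor
  expect_false(significance_call(2.0, 0.06, cfg))    # over the q ceiling
  expect_true(significance_call(-1.0, 0.05, cfg))    # boundary inclusive

  curve <- analysis_config(sig_mode = "curve", curve_steepness = 2)
  # at |lfc| = lfc_min the effective threshold is exactly 0
  expect_false(significance_call(1, 1e-12, curve))
  # threshold approaches q_max from below at high |lfc|
  expect_true(significance_call(50, 0.0499, curve))
  expect_false(significance_call(50, 0.051, curve))
  # mid fold changes need stronger q: threshold at |lfc| = 1.5 is
  # 0.05 * (1 - 2^-1) = 0.025
  expect_true(significance_call(1.5, 0.024, curve))
  expect_false(significance_call(1.5, 0.026, curve))
})

test_that("cycle aggregation averages lfc, takes medians, and needs a strict majority", {
  mk <- function(lfc, p, q) {
    structure(data.frame(protein = paste0("P", seq_along(lfc)), lfc = lfc,
                         s2 = 1, df = 4, s2_post = 1, t = lfc, p = p, q = q),
              class = c("cycle_de_result", "data.frame"))
  }
  cfg <- analysis_config(n_cycles = 3)
  # 3 proteins x 3 cycles; hand-averaged lfc
  cyc <- list(mk(c(2.0, 0.1, -1.5), c(1e-4, 0.9, 1e-3), c(1e-3, 0.95, 1e-2)),
              mk(c(2.2, 0.2, -1.6), c(1e-4, 0.8, 1e-3), c(1e-3, 0.90, 1e-2)),
              mk(c(1.8, 0.0, -1.7), c(1e-4, 0.7, 1e-3), c(1e-3, 0.85, 1e-2)))
  de <- aggregate_cycles(cyc, cfg)
  expect_equal(de$lfc, c(2.0, 0.1, -1.6))
  expect_equal(de$q, c(1e-3, 0.90, 1e-2))
  expect_equal(de$n_cycles_significant, c(3L, 0L, 3L))
  expect_equal(de$significant, c(TRUE, FALSE, TRUE))
  expect_equal(de$direction, c("up", "ns", "down"))
  expect_true(all(de$q >= de$p))

  # single cycle: aggregation is the identity on that cycle's calls
  one <- aggregate_cycles(cyc[1], analysis_config(n_cycles = 1))
  expect_equal(one$lfc, cyc[[1]]$lfc)
  expect_equal(one$significant, unname(significance_call(cyc[[1]]$lfc,
                                                         cyc[[1]]$q, cfg)))

  # exactly half the cycles significant is not a strict majority
  half <- list(mk(2, 1e-4, 1e-3), mk(2, 1e-4, 1e-3),
               mk(2, 0.5, 0.6), mk(2, 0.5, 0.6))
  de_half <- aggregate_cycles(half, analysis_config(n_cycles = 4))
  expect_equal(de_half$n_cycles_significant, 2L)
  expect_false(de_half$significant)

  expect_error(aggregate_cycles(list(mk(1, 0.5, 0.5), {
    x <- mk(1, 0.5, 0.5); x$protein <- "OTHER"; x
  })), "different protein sets")
})

test_that("threshold counting uses strict inequalities on lfc and raw p", {
  cfg <- analysis_config()
  tab <- data.frame(lfc = c(0.6, -0.6, 0.4), p = c(0.01, 0.2, 0.001))
  counts <- count_by_thresholds(tab, cfg)
  expect_equal(counts, list(down = 1L, up = 1L, significant = 2L,
                            nonsignificant = 1L, down_sig = 0L, up_sig = 1L))

  # boundary values are excluded by strictness; empty table gives zeros
  edge <- data.frame(lfc = c(0.5, -0.5), p = c(0.05, 0.04))
  expect_equal(count_by_thresholds(edge, cfg)$up, 0L)
  expect_equal(count_by_thresholds(edge, cfg)$significant, 1L)
  zero <- count_by_thresholds(data.frame(lfc = numeric(), p = numeric()), cfg)
  expect_true(all(unlist(zero) == 0L))

  # invariant to row order
  perm <- tab[c(3, 1, 2), ]
  expect_equal(count_by_thresholds(perm, cfg), counts)
})
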