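test_that("missing cells are classified by per-condition detection count", {
  v <- matrix(NA_real_, 4, 6)
  v[1, ] <- c(NA, NA, NA, 20, 21, 20)       # 0 detections in a -> mnar x3
  v[2, ] <- c(18, 19, NA, 20, 21, 20)       # 2 detections, 1 missing -> mle
  v[3, ] <- c(18, NA, NA, 20, NA, 20)       # 1 detection in a -> mnar x2
  v[4, ] <- c(18, 19, 20, 20, 21, 20)       # complete -> observed only
  m <- tiny_matrix(v)
  lab <- classify_missing(m)

  expect_equal(unname(lab[1, 1:3]), rep("mnar_rule", 3))
  expect_equal(unname(lab[2, 3]), "mle_rule")
  expect_equal(unname(lab[3, 2:3]), rep("mnar_rule", 2))
  expect_equal(unname(lab[3, 5]), "mle_rule")
  expect_true(all(lab[4, ] == "observed"))
  expect_identical(lab == "observed", !is.na(m$values))
})

test_that("column statistics use observed cells and the n-1 denominator", {
  v <- matrix(rnorm(6 * 6, 20), 6, 6)
  v[1:4, 1] <- c(10, 12, NA, NA)
  v[5:6, 1] <- NA
  m <- tiny_matrix(v)
  cs <- column_stats(m)
  expect_equal(cs$mean[1], 11)
  expect_equal(cs$sd[1], sqrt(2))
  expect_equal(cs$n_obs[1], 2L)

  # agreement with an independent two-pass computation on 1,000 values
  set.seed(33)
  x <- rnorm(1000, 20, 3)
  big <- tiny_matrix(cbind(matrix(x, 500, 2), matrix(rnorm(2000, 20), 500, 4)))
  cs2 <- column_stats(big)
  twopass_mean <- sum(x[1:500]) / 500
  twopass_sd <- sqrt(sum((x[1:500] - twopass_mean)^2) / 499)
  expect_equal(cs2$mean[1], twopass_mean, tolerance = 1e-12)
  expect_equal(cs2$sd[1], twopass_sd, tolerance = 1e-12)

  v[, 2] <- NA; v[1, 2] <- 20
  expect_error(column_stats(tiny_matrix(v)), "fewer than 2 observed")
})

test_that("down-shifted draws have the configured location and width", {
  set.seed(5)
  x <- draw_mnar(1e5, col_mean = 20, col_sd = 2)
  # closed form with default constants: mean 20 - 2.5*2 = 15, sd 0.3*2 = 0.6
  se_mean <- 0.6 / sqrt(1e5)
  expect_lt(abs(mean(x) - 15), 3 * se_mean)
  se_sd <- 0.6 / sqrt(2 * (1e5 - 1))
  expect_lt(abs(sd(x) - 0.6), 3 * se_sd)

  # degenerate Gaussian at sd = 0
  expect_equal(draw_mnar(5, 20, 0), rep(20, 5))
})

test_that("MLE draws come from the n-denominator Gaussian fit of the block", {
  expect_equal(draw_mle(c(5, 5), n = 3), rep(5, 3))  # fitted sd 0
  expect_error(draw_mle(c(4), n = 1), ">= 2 observed")

  set.seed(6)
  x <- draw_mle(c(4, 6), n = 1e5)   # MLE fit: Normal(5, 1)
  expect_lt(abs(mean(x) - 5), 3 / sqrt(1e5))
  expect_lt(abs(sd(x) - 1), 3 / sqrt(2 * (1e5 - 1)))

  # fitted parameters equal a closed-form MLE on 100 random blocks
  set.seed(7)
  for (i in 1:100) {
    vals <- rnorm(sample(2:6, 1), 20, 2)
    mu <- sum(vals) / length(vals)
    sd_mle <- sqrt(sum((vals - mu)^2) / length(vals))
    set.seed(1000 + i); got <- draw_mle(vals, n = 2)
    set.seed(1000 + i); want <- rnorm(2, mu, sd_mle)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("cycles are reproducible, differ stochastically, and preserve observed cells", {
  set.seed(12)
  v <- matrix(rnorm(120, 20, 2), 20, 6)
  v[sample(120, 25)] <- NA
  m <- tiny_matrix(v)
  cfg <- analysis_config(n_cycles = 4, seed = 42)

  imp <- run_cycles(m, config = cfg)
  expect_length(imp$cycles, 4L)
  for (cyc in imp$cycles) {
    expect_false(anyNA(cyc))
    expect_identical(cyc[!is.na(v)], v[!is.na(v)])  # observed untouched
  }
  # same seed -> bit-identical; imputed values differ between cycles
  imp2 <- run_cycles(m, config = cfg)
  expect_identical(imp$cycles, imp2$cycles)
  miss <- which(is.na(v))
  expect_false(identical(imp$cycles[[1]][miss], imp$cycles[[2]][miss]))

  # complete input -> all cycles identical to the input
  full <- tiny_matrix(matrix(rnorm(36, 20), 6, 6))
  impf <- run_cycles(full, config = cfg)
  expect_identical(impf$cycles[[3]], full$values)
})

test_that("imputed values follow the rule for their label", {
  # column means/sds known; protein 1 fully missing in condition a (mnar),
  # protein 2 has 2 detections + 1 missing in condition a (mle)
  set.seed(13)
  v <- matrix(rnorm(600 * 6, 20, 2), 600, 6)
  v[1, 1:3] <- NA
  v[2, 3] <- NA
  m <- tiny_matrix(v)
  cfg <- analysis_config(n_cycles = 400, seed = 3)
  cs <- column_stats(m)
  imp <- run_cycles(m, config = cfg)

  # mnar draws in column 1 converge to mean - 2.5 sd, width 0.3 sd
  mnar_draws <- vapply(imp$cycles, function(x) x[1, 1], numeric(1))
  want_mu <- cs$mean[1] - 2.5 * cs$sd[1]
  want_sd <- 0.3 * cs$sd[1]
  expect_lt(abs(mean(mnar_draws) - want_mu), 3 * want_sd / sqrt(400))
  expect_lt(abs(sd(mnar_draws) - want_sd), 3 * want_sd / sqrt(2 * 399))

  # mle draws reproduce the block's MLE fit
  blk <- v[2, 1:2]
  mle_draws <- vapply(imp$cycles, function(x) x[2, 3], numeric(1))
  mu <- mean(blk); s <- sqrt(mean((blk - mu)^2))
  expect_lt(abs(mean(mle_draws) - mu), 3 * s / sqrt(400))
  expect_lt(abs(sd(mle_draws) - s), 4 * s / sqrt(2 * 399))
})
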