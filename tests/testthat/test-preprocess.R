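test_that("position mapping is affine with endpoints 0 and 1", {
  expect_equal(map_positions(c(100, 200, 300)), c(0, 0.5, 1))
  expect_equal(map_positions(c(0, 10)), c(0, 1))
  expect_equal(map_positions(c(100, 150, 300)), c(0, 0.25, 1))
  expect_error(map_positions(100), "two positions")
  expect_error(map_positions(c(100, 100, 200)), "strictly increasing")
})

test_that("grid depth is the smallest dyadic cover of n", {
  expect_equal(grid_depth(5209), 13L)   # 2^13 = 8192 >= 5209
  expect_equal(grid_depth(8), 3L)
  expect_equal(grid_depth(9), 4L)
})

test_that("interpolation is the identity on an aligned dyadic grid", {
  J <- 4
  tk <- (seq_len(2^J) - 0.5) / 2^J
  vals <- matrix(rnorm(3 * 2^J), 3)
  g <- interpolate_to_grid(tk, vals)
  expect_equal(g$J, J)
  expect_equal(g$values, vals)
})

test_that("interpolation reproduces linear signals exactly and never overshoots", {
  set.seed(81)
  pos <- sort(runif(37))
  pos01 <- map_positions(pos)
  a <- 0.7; b <- -2.2
  vals <- rbind(a + b * pos01)
  g <- interpolate_to_grid(pos01, vals)
  expect_equal(drop(g$values), a + b * g$grid, tolerance = 1e-12)

  vals2 <- rbind(runif(37, 0, 2))
  g2 <- interpolate_to_grid(pos01, vals2)
  expect_true(all(g2$values >= min(vals2) - 1e-12))
  expect_true(all(g2$values <= max(vals2) + 1e-12))
})

test_that("a 5209-SNP region is gridded to length 8192", {
  pos01 <- seq(0, 1, length.out = 5209)
  g <- interpolate_to_grid(pos01, matrix(0, 1, 5209))
  expect_equal(length(g$grid), 8192L)
})

test_that("interpolation rejects degenerate input", {
  expect_error(interpolate_to_grid(numeric(0), matrix(0, 1, 0)), "no SNPs")
  expect_error(interpolate_to_grid(c(0, 1), matrix(c(1, NA), 1)), "non-finite")
  expect_error(interpolate_to_grid(c(0, 1), matrix(1:2, 1), snp_var = c(-1, 0)),
               "negative")
})

test_that("universal-threshold shrinkage matches the closed form", {
  thr <- sqrt(2 * log(1024))          # 3.72330 at unit variance
  expect_equal(visushrink(5, 1, 1024), 5 - thr, tolerance = 1e-6)
  expect_equal(visushrink(5, 1, 1024), 1.276703, tolerance = 1e-6)
  expect_equal(visushrink(1, 1, 1024), 0)                 # sub-threshold kill
  expect_equal(visushrink(-5, 1, 1024), -(5 - thr))       # odd symmetry
  x <- matrix(rnorm(20), 4)
  expect_equal(visushrink(x, 0, 1024), x)                 # zero variance: no-op
  expect_equal(visushrink(5, 1, 1024, mode = "hard"), 5)  # hard keeps survivors
  expect_equal(visushrink(1, 1, 1024, mode = "hard"), 0)
  expect_error(visushrink(5, -1, 1024), "non-negative")
})

test_that("coefficient variances propagate the diagonal SNP noise", {
  # aligned grid, iq-derived variances: coefficient variance is the row-sum
  # of squared transform weights times the per-SNP variance
  J <- 3
  tk <- (seq_len(2^J) - 0.5) / 2^J
  snp_var <- runif(2^J, 0, 0.2)
  g <- interpolate_to_grid(tk, matrix(0, 1, 2^J), snp_var = snp_var)
  cv <- coefficient_variances(g, S = 2)
  oracle <- as.numeric((naive_c_matrix(J, 2)^2) %*% snp_var)
  expect_equal(cv, oracle, tolerance = 1e-12)
})

test_that("rank-based inverse-normal transform follows the Blom formula", {
  out <- quantile_transform(cbind(c(10, 20, 30)))
  expect_equal(drop(out$values), qnorm((1:3 - 3 / 8) / 3.25),
               tolerance = 1e-12)
  expect_equal(drop(out$values), c(-0.8694238, 0, 0.8694238), tolerance = 1e-6)

  # strictly increasing columns stay strictly increasing
  x <- cbind(sort(rnorm(50)))
  expect_true(all(diff(drop(quantile_transform(x)$values)) > 0))

  # a column already equal to its normal scores is a fixed point
  ns <- qnorm((1:50 - 3 / 8) / (50 + 1 / 4))
  expect_equal(drop(quantile_transform(cbind(ns))$values), ns)

  # degenerate columns are flagged and zeroed
  out2 <- quantile_transform(cbind(rnorm(20), rep(1, 20)))
  expect_equal(out2$excluded, 2L)
  expect_equal(out2$values[, 2], rep(0, 20))
})

test_that("normalised columns are marginally standard normal", {
  set.seed(82)
  K <- 200
  x <- cbind(rexp(K), rnorm(K, 5, 3), runif(K))
  qn <- quantile_transform(x)$values
  for (j in 1:3) {
    expect_lt(abs(mean(qn[, j])), 3 / sqrt(K))
    expect_gt(var(qn[, j]), 0.8)
    expect_lt(var(qn[, j]), 1.2)
    expect_gt(suppressWarnings(ks.test(qn[, j], "pnorm")$p.value), 0.01)
  }
})

test_that("the depth rule reproduces the worked spacing examples", {
  d1 <- choose_depth(1e6, 202)
  expect_equal(d1$S, 9L)
  expect_equal(d1$snps_per_coeff, 9.7, tolerance = 0.005)
  d2 <- choose_depth(1e6, 3525)
  expect_equal(d2$S, 5L)
  expect_equal(d2$snps_per_coeff, 8.9, tolerance = 0.005)
  expect_equal(choose_depth(1e6, 100)$S, 10L)
  expect_error(choose_depth(1e4, 5e3), "enlarge the region")
})

test_that("the full preprocess pipeline reduces to interpolation + Haar + rank normalisation on clean input", {
  reg <- dyadic_region(K = 60, J = 5, seed = 83)
  co <- ws_preprocess(reg, S = 4)
  # oracle route built from independent primitives: stats::approx for the
  # gridding, the explicit sum-pyramid rows, and the Blom formula
  pos01 <- (reg$positions - reg$positions[1]) /
    (reg$positions[32] - reg$positions[1])
  tk <- (seq_len(32) - 0.5) / 32
  gridded <- t(apply(reg$dosages, 1, function(y) {
    stats::approx(pos01, y, xout = tk, rule = 2)$y
  }))
  oracle_coefs <- t(naive_c_matrix(5, 4) %*% t(gridded))
  oracle_qn <- apply(oracle_coefs, 2, function(col) {
    qnorm((rank(col) - 3 / 8) / (60 + 1 / 4))
  })
  expect_equal(unname(co$coef), unname(oracle_qn), tolerance = 1e-10)
  expect_equal(co$excluded, integer(0))
  expect_equal(colnames(co$coef)[1:4], c("s0_l1", "s1_l1", "s1_l2", "s2_l1"))
})

test_that("region construction validates its invariants", {
  expect_error(genotype_region(matrix(3, 1, 1), 100), "\\[0, 2\\]")
  expect_error(genotype_region(matrix(1, 1, 2), c(200, 100)), "increasing")
  expect_error(genotype_region(matrix(1, 1, 1), 100, iq = 1.5), "iq")
})
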