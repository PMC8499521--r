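fake_fit <- function(pi_alt = 0.1, mu_alt = 0.05, s2n = 1e-4, s2a = 1e-2) {
  structure(list(pi_alt = pi_alt, mu_alt = mu_alt, sigma2_null = s2n,
                 sigma2_alt = s2a, v = 1e-4, k = 100),
            class = "ws_mixture")
}

test_that("the evidence statistic matches its closed-form special cases", {
  S <- 3
  M <- 2^(S + 1) - 1
  fit <- fake_fit()
  # all pi_tilde zero and constant null density: L_h = -(S+1) * phi0
  beta <- rep(0.01, M)
  phi0 <- dnorm(0.01, 0, sqrt(fit$sigma2_null))
  expect_equal(compute_Lh(beta, rep(0, M), fit, S), -(S + 1) * phi0)

  # single coefficient, pi_tilde = 1: the alternative density alone
  expect_equal(compute_Lh(0.02, 1, fit, 0),
               dnorm(0.02, fit$mu_alt, sqrt(fit$sigma2_alt)))
})

test_that("horizontal and vertical summaries match the worked examples", {
  expect_equal(compute_ph(rep(0, 7), 2), 0)
  expect_equal(compute_ph(rep(1, 7), 2), 3)       # each scale contributes 1
  pt <- rep(0, 7); pt[2] <- 0.6                   # only (s=1, l=1)
  expect_equal(compute_ph(pt, 2), 0.3)

  expect_equal(compute_pv(rep(0, 7), 2), 0)
  expect_equal(compute_pv(rep(1, 7), 2), 1)       # S=2: one sub-region
  expect_equal(subregion_weights(2)$n_k, 6L)      # 2 + 4 member pairs
  for (S in c(3, 5, 9)) {
    expect_equal(compute_pv(rep(1, 2^(S + 1) - 1), S), S - 1)
  }
})

test_that("vectorised summaries agree with brute-force double loops", {
  set.seed(111)
  for (S in c(2, 4, 6, 9)) {
    M <- 2^(S + 1) - 1
    pt <- pmax(runif(M) - 0.5, 0)
    beta <- rnorm(M, 0, 0.01)
    fit <- fake_fit()
    expect_equal(compute_ph(pt, S), brute_ph(pt, S), tolerance = 1e-12)
    expect_equal(compute_pv(pt, S), brute_pv(pt, S), tolerance = 1e-12)
    expect_equal(compute_Lh(beta, pt, fit, S), brute_Lh(beta, pt, fit, S),
                 tolerance = 1e-12)
  }
})

test_that("excluded coefficients contribute nothing to the evidence", {
  S <- 2
  beta <- c(NA, rnorm(6, 0, 0.01))
  pt <- rep(0.2, 7)
  fit <- fake_fit()
  expect_equal(compute_Lh(beta, pt, fit, S),
               brute_Lh(beta, pt, fit, S))
})

test_that("the composite statistic is L_h plus the lambda-weighted minimum", {
  expect_equal(compute_T(1, 0.4, 0.2, 5), 2)
  expect_equal(compute_T(1, 0.2, 0.4, 5), 2)          # symmetric in the swap
  expect_equal(compute_T(-3.2, 0.4, 0.2, 0), -3.2)    # lambda = 0
  expect_error(compute_T(1, 1, 1, -2), "lambda")
})

test_that("the compiled batch path agrees with the R statistic path", {
  set.seed(112)
  S <- 4
  M <- 2^(S + 1) - 1
  K <- 400
  v <- 1 / (K - 1)
  betas <- matrix(rnorm(8 * M, 0, sqrt(v)), 8, M)
  betas[5, 1:6] <- rnorm(6, 8 * sqrt(v), sqrt(300 * v))  # one signal row
  scale <- rep.int(0:S, 2^(0:S))
  res <- wavescreen:::.em_batch_stats_cpp(
    betas, v = v, wh = 2^(-scale), wv = subregion_weights(S)$wv,
    thr = pi_threshold(K, scale))
  for (i in seq_len(nrow(betas))) {
    f <- fit_constrained_mixture(betas[i, ], v = v)
    post <- threshold_posteriors(posterior_probabilities(betas[i, ], f), K)
    expect_equal(unname(res[i, "Lh"]),
                 compute_Lh(betas[i, ], post$pi_tilde, f, S),
                 tolerance = 1e-8)
    expect_equal(unname(res[i, "ph"]), compute_ph(post$pi_tilde, S),
                 tolerance = 1e-8)
    expect_equal(unname(res[i, "pv"]), compute_pv(post$pi_tilde, S),
                 tolerance = 1e-8)
  }
})

test_that("null beta draws have the right shape and marginal variance", {
  set.seed(113)
  S <- 5
  v <- 2.5e-3
  for (m in c("random-signal", "theoretical")) {
    B <- simulate_null_betas(4000, S = S, v = v, method = m)
    expect_equal(dim(B), c(4000L, 63L))
    ratio <- apply(B, 2, var) / v
    if (m == "random-signal") {
      expect_true(all(abs(ratio - 1) < 1e-10))   # exact by column rescaling
    } else {
      expect_true(all(ratio > 0.9 & ratio < 1.1))
    }
  }
})

test_that("the null simulation methods agree on an LD-free region", {
  set.seed(114)
  m <- ld_block_model(n_snps = 256, n_blocks = 256, rho = 0,
                      iq_range = c(1, 1), spacing = 200)
  reg <- simulate_genotypes(600, m)
  co <- ws_preprocess(reg, S = 5)
  v <- 1 / 599
  d1 <- ws_null_statistics(6000, S = 5, v = v, K = 600,
                           method = "random-signal", seed = 1)
  d2 <- ws_null_statistics(6000, S = 5, v = v, K = 600,
                           method = "empirical-cov", coefs = co, seed = 2)
  d3 <- ws_null_statistics(6000, S = 5, v = v, K = 600,
                           method = "theoretical", seed = 3)
  ks <- function(a, b) suppressWarnings(ks.test(a, b)$statistic)
  expect_lt(ks(d1$Lh, d2$Lh), 0.05)
  expect_lt(ks(d1$Lh, d3$Lh), 0.05)
  expect_lt(ks(d2$Lh, d3$Lh), 0.05)
})

test_that("lambda calibration handles the degenerate grid and extreme lambdas", {
  set.seed(115)
  Lh <- rnorm(20000, -50, 5)
  minp <- ifelse(runif(20000) < 0.01, runif(20000, 0, 0.5), 0)

  cal0 <- calibrate_lambda(Lh, minp, lambda_grid = 0)
  expect_equal(cal0$lambda_star, 0)
  expect_equal(cal0$null_mean, mean(Lh))
  expect_equal(cal0$null_sd, sd(Lh))

  # an absurdly large lambda makes the first bin the fullest: the criterion
  # must reject it
  lam <- 1e9 * sd(Lh) / sd(minp)
  Th <- Lh + lam * minp
  p <- pnorm(Th, mean(Th), sd(Th), lower.tail = FALSE)
  expect_lt(wavescreen:::first_bin_rank(p), cal0$first_bin_rank_ref)
  cal <- calibrate_lambda(Lh, minp)
  expect_lt(cal$lambda_star, lam)
})

test_that("calibrated p-values are the upper normal tail", {
  cal <- structure(list(lambda_star = 1, null_mean = -10, null_sd = 2),
                   class = "ws_calibration")
  expect_equal(region_pvalue(-10, cal), 0.5)
  expect_equal(region_pvalue(-10 + 1.959964 * 2, cal), 0.025, tolerance = 1e-6)
  Ts <- seq(-20, 5, length.out = 50)
  expect_true(all(diff(region_pvalue(Ts, cal)) < 0))
})

test_that("calibrations survive a JSON round trip", {
  set.seed(116)
  d <- ws_null_statistics(3000, S = 3, v = 1e-3, K = 200,
                          method = "random-signal", seed = 5)
  cal <- calibrate_lambda(d$Lh, d$minp, method = "random-signal", seed = 5)
  path <- tempfile(fileext = ".json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$lambda_star, cal$lambda_star)
  expect_equal(back$null_mean, cal$null_mean)
  expect_equal(back$null_sd, cal$null_sd)
  expect_equal(region_pvalue(-1, back), region_pvalue(-1, cal))
})
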