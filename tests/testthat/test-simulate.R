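test_that("simulated dosages respect the model contracts", {
  set.seed(131)
  m <- ld_block_model(n_snps = 120, n_blocks = 6, spacing = 250)
  reg <- simulate_genotypes(400, m)
  expect_true(all(reg$dosages >= 0 & reg$dosages <= 2))
  expect_equal(ncol(reg$dosages), 120L)
  expect_equal(length(attr(reg, "block")), 120L)
  expect_true(all(reg$iq >= 0.8 & reg$iq <= 1))
  expect_equal(diff(reg$positions), rep(250, 119))
  expect_error(ld_block_model(rho = 1.2), "rho")
  expect_error(ld_block_model(maf_range = c(0, 0.6)), "MAF")
})

test_that("within-block dosage correlation matches a two-SNP copula oracle and blocks are independent", {
  set.seed(132)
  # oracle: direct 2-SNP simulation from the same latent construction
  oracle_r <- local({
    n <- 2e5
    u <- rnorm(n)
    z1 <- sqrt(0.8) * u + sqrt(0.2) * rnorm(n)
    z2 <- sqrt(0.8) * u + sqrt(0.2) * rnorm(n)
    maf <- 0.25
    cut1 <- qnorm((1 - maf)^2); cut2 <- qnorm(1 - maf^2)
    g1 <- (z1 > cut1) + (z1 > cut2)
    g2 <- (z2 > cut1) + (z2 > cut2)
    cor(g1, g2)
  })
  m <- ld_block_model(n_snps = 240, n_blocks = 8, rho = 0.8,
                      maf_range = c(0.25, 0.25), iq_range = c(1, 1))
  reg <- simulate_genotypes(6000, m)
  cc <- cor(reg$dosages)
  block <- attr(reg, "block")
  same <- outer(block, block, "==") & upper.tri(cc)
  diff_b <- outer(block, block, "!=") & upper.tri(cc)
  expect_lt(abs(mean(cc[same]) - oracle_r), 0.1)
  expect_lt(abs(mean(cc[diff_b])), 0.05)
  expect_gt(mean(cc[same]), mean(cc[diff_b]) + 0.3)
})

test_that("phenotype scores hit the requested variance explained", {
  set.seed(133)
  m <- ld_block_model(n_snps = 300, n_blocks = 12)
  reg <- simulate_genotypes(8000, m)
  ph <- simulate_phenotype(reg, 10, "MD", "high-LD")
  expect_gt(ph$achieved_ve, 0.002)
  expect_lt(ph$achieved_ve, 0.009)
  # empirical R^2 of the score on phi agrees
  score <- rowSums(reg$dosages[, ph$causal, drop = FALSE])
  r2 <- summary(lm(ph$phi ~ score))$r.squared
  expect_gt(r2, 0.002)
  expect_lt(r2, 0.009)
})

test_that("effect-direction models behave as declared", {
  set.seed(134)
  m <- ld_block_model(n_snps = 200, n_blocks = 10)
  reg <- simulate_genotypes(300, m)
  md <- simulate_phenotype(reg, 12, "MD", "random-LD")
  expect_true(all(md$signs == 1))
  rd <- simulate_phenotype(reg, 20, "RD", "random-LD")
  expect_true(any(rd$signs == 1) && any(rd$signs == -1))
  expect_equal(length(unique(rd$causal)), 20L)
})

test_that("high-LD selection clusters causal SNPs within eligible blocks", {
  set.seed(135)
  m <- ld_block_model(n_snps = 280, n_blocks = 14)
  reg <- simulate_genotypes(100, m)
  ph <- simulate_phenotype(reg, 8, "MD", "high-LD")
  blocks_used <- unique(attr(reg, "block")[ph$causal])
  expect_lte(length(blocks_used), 2L)   # 8 causal packed 5-per-block
  ph2 <- simulate_phenotype(reg, 3, "MD", "high-LD")
  expect_equal(length(unique(attr(reg, "block")[ph2$causal])), 1L)
})

test_that("the null phenotype path is exactly standard normal noise", {
  set.seed(136)
  reg <- simulate_genotypes(5000, ld_block_model(n_snps = 50, n_blocks = 5))
  ph <- simulate_phenotype(reg, 0, "MD", "high-LD")
  expect_equal(length(ph$causal), 0L)
  expect_equal(ph$achieved_ve, 0)
  expect_gt(shapiro.test(ph$phi[1:2000])$p.value, 1e-4)
  expect_lt(abs(mean(ph$phi)), 0.05)
  expect_lt(abs(sd(ph$phi) - 1), 0.05)
})

test_that("the type-I experiment is calibrated at generous alpha and reproducible", {
  m <- ld_block_model(n_snps = 320, n_blocks = 8, spacing = 300)
  res <- run_type1_experiment(K = 300, n_reps = 400,
                              alpha_levels = c(0.5, 0.05),
                              model = m, n_calib = 4000, seed = 51)
  # alpha = 0.5 is the median check; the null composite statistic is mildly
  # skewed, so the normal-fit median sits slightly off the true median
  expect_lt(abs(res$rate[res$alpha == 0.5] - 0.5), 0.12)
  expect_lt(res$rate[res$alpha == 0.05], 0.12)
  expect_equal(res$mc_se, sqrt(res$alpha * (1 - res$alpha) / 400))

  res2 <- run_type1_experiment(K = 300, n_reps = 400,
                               alpha_levels = c(0.5, 0.05),
                               model = m, n_calib = 4000, seed = 51)
  expect_equal(res$rate, res2$rate)     # same seed, same rates
})

test_that("power is 1 at significance 1 and the table has the requested shape", {
  m <- ld_block_model(n_snps = 320, n_blocks = 8, spacing = 300)
  pw <- run_power_experiment(K_grid = 300, models = c("MD", "RD"),
                             causal_bins = list("1" = 1, "6-10" = 6:10),
                             n_reps = 30, significance = 1,
                             model = m, n_calib = 3000, seed = 52)
  expect_equal(nrow(pw), 4L)
  expect_true(all(pw$power == 1))
  expect_setequal(unique(pw$model), c("MD", "RD"))
})
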