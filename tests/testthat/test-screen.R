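test_that("VCF dosages, IQ filtering and multi-allelic skipping work", {
  path <- write_toy_vcf(tempfile(fileext = ".vcf"))
  reg <- suppressWarnings(read_genotypes(path))
  # rs3 (R2 = 0.75) filtered, rs5 multi-allelic skipped -> 3 SNPs, 2 samples
  expect_equal(dim(reg$dosages), c(2L, 3L))
  expect_equal(reg$positions, c(100, 200, 300))
  expect_equal(unname(reg$dosages[, 1]), c(0.1, 1.2))
  expect_equal(reg$iq, c(0.99, 0.95, 0.90))
  expect_warning(read_genotypes(path), "multi-allelic")

  # region restriction
  reg2 <- suppressWarnings(read_genotypes(path, chrom = "1",
                                          start = 150, end = 350))
  expect_equal(reg2$positions, c(200, 300))
  expect_error(suppressWarnings(read_genotypes(path, start = 5000, end = 6000)),
               "no SNPs")
})

test_that("hard genotype calls convert to additive dosages", {
  path <- write_toy_vcf_gt(tempfile(fileext = ".vcf"))
  reg <- read_genotypes(path)
  expect_equal(unname(reg$dosages),
               rbind(c(0, 2, 1), c(1, 1, 2)))
  expect_equal(reg$iq, rep(1, 3))    # IQ defaults to 1 when absent
})

test_that("dosage TSVs round-trip exactly", {
  reg <- dyadic_region(K = 5, J = 3, seed = 21)
  path <- tempfile(fileext = ".tsv")
  write_dosage_tsv(reg, path)
  back <- read_genotypes(path)
  expect_equal(unname(back$dosages), unname(reg$dosages))
  expect_equal(back$positions, reg$positions)
  expect_equal(back$iq, reg$iq)
})

test_that("window tiling follows the half-overlap stepping rule", {
  expect_equal(nrow(define_regions(numeric(0))), 0L)

  pos <- seq(200, 3e6, by = 200)
  reg <- define_regions(pos, region_size = 1e6, overlap_fraction = 0.5,
                        max_gap = 1e4)
  expect_equal(reg$start, c(1, 500001, 1000001, 1500001, 2000001))
  expect_equal(reg$end, reg$start + 1e6 - 1)
  expect_true(all(reg$max_gap_ok))
  expect_equal(attr(reg, "excluded_fraction"), 0)

  # a 15 kb gap excludes exactly the windows that span it
  pos_gap <- pos[pos < 1.2e6 | pos > 1.215e6]
  reg_gap <- define_regions(pos_gap, region_size = 1e6,
                            overlap_fraction = 0.5, max_gap = 1e4)
  expect_false(any(reg_gap$start %in% c(500001, 1000001)))
  expect_true(all(c(1, 1500001, 2000001) %in% reg_gap$start))
})

test_that("Fisher's method matches the chi-square closed form", {
  m1 <- fisher_meta(c(1, 1))
  expect_equal(m1$chi2, 0)
  expect_equal(m1$df, 4L)
  expect_equal(m1$p_value, 1)

  # single cohort: the identity
  expect_equal(fisher_meta(0.01)$p_value, 0.01, tolerance = 1e-10)

  m2 <- fisher_meta(c(0.05, 0.05))
  expect_equal(m2$chi2, -4 * log(0.05), tolerance = 1e-10)
  expect_equal(m2$chi2, 11.98293, tolerance = 1e-5)
  expect_equal(m2$p_value, pchisq(-4 * log(0.05), 4, lower.tail = FALSE),
               tolerance = 1e-10)

  expect_warning(fisher_meta(c(0, 0.5)), "clamped")
  expect_error(fisher_meta(c(0.5, 2)), "0, 1")
})

test_that("screening runs end to end, deterministically, with tidy output", {
  set.seed(121)
  m <- ld_block_model(n_snps = 700, n_blocks = 10, spacing = 300, start = 1)
  gen <- simulate_genotypes(250, m)
  phi <- rnorm(250)
  run <- function(prefix) {
    ws_screen(gen, phi, region_size = 65536, overlap_fraction = 0.5,
              max_gap = 5e3, min_snps = 64, S = 4, n_calib = 3000,
              seed = 99, out_prefix = prefix)
  }
  p1 <- tempfile(); p2 <- tempfile()
  tab <- run(p1)
  expect_s3_class(tab, "tbl_df")
  expect_gt(nrow(tab), 2)
  expect_true(all(tab$status == "ok"))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  expect_true(!is.unsorted(tab$start))
  # same seed, byte-identical outputs
  run(p2)
  expect_identical(readLines(paste0(p1, ".tsv")), readLines(paste0(p2, ".tsv")))
  # screen table round trip through the TSV
  back <- utils::read.delim(paste0(p1, ".tsv"))
  expect_equal(back$p_value, tab$p_value, tolerance = 1e-12)
  expect_true(file.exists(paste0(p1, "_manifest.json")))
})

test_that("region testing produces a complete tidy result", {
  set.seed(122)
  reg <- dyadic_region(K = 120, J = 6, seed = 3)
  co <- ws_preprocess(reg, S = 4)
  d <- build_design(rnorm(120))
  cal <- ws_calibrate(3000, S = 4, v = d$v, K = 120,
                      method = "random-signal", seed = 4)
  res <- ws_test_region(co, d, cal)
  expect_s3_class(res, "ws_result")
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
  expect_equal(res$T, res$Lh + cal$lambda_star * res$minp)

  tab <- export_plot_table(res)
  expect_equal(nrow(tab), 31L)
  # spans at each scale partition the region exactly
  for (s in 0:4) {
    sp <- tab[tab$scale == s, ]
    expect_equal(sp$start[1], res$start)
    expect_equal(sp$end[nrow(sp)], res$end + 1, tolerance = 1e-9)
    if (nrow(sp) > 1) expect_equal(sp$start[-1], sp$end[-nrow(sp)])
  }
  expect_equal(tab$highlighted, tab$pi_tilde > 0)

  # broom-style accessors and the pyramid plot
  expect_equal(tidy(res), tab)
  g <- glance(res)
  expect_equal(nrow(g), 1L)
  expect_equal(g$p_value, res$p_value)
  expect_equal(nrow(tidy(res$fit)), 2L)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(glance(cal), "tbl_df")
})

test_that("an S=2 result yields seven plot rows and no highlights when all pi_tilde are zero", {
  post <- tibble::tibble(scale = rep.int(0:2, c(1, 2, 4)),
                         loc = c(1, 1:2, 1:4),
                         beta = rnorm(7, 0, 0.01),
                         excluded = FALSE, pi_hat = 0, pi_tilde = 0)
  res <- structure(list(posteriors = post, start = 1, end = 1000),
                   class = "ws_result")
  tab <- export_plot_table(res)
  expect_equal(nrow(tab), 7L)
  expect_equal(sum(tab$highlighted), 0L)
})

test_that("sample mismatches are reported, not silently dropped", {
  gen <- dyadic_region(K = 4, J = 3, seed = 5)
  rownames(gen$dosages) <- paste0("id", 1:4)
  pheno <- tibble::tibble(sample_id = c("id1", "id2", "idX", "id4"),
                          value = rnorm(4))
  expect_error(ws_screen(gen, pheno, S = 2), "sample mismatch")
})
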