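#' Tile a chromosome into overlapping screening windows
#'
#' Builds half-overlapping windows of `region_size` base pairs (step
#' `region_size * (1 - overlap_fraction)`) starting at position 1, keeping
#' only windows that end within the observed positions. Windows containing
#' fewer than `min_snps` SNPs, or any adjacent-SNP gap larger than `max_gap`
#' (purely interpolated stretches), are excluded; the excluded fraction is
#' reported as an attribute. Overlap guarantees that a signal sitting on any
#' window boundary is interior to the neighbouring window.
#'
#' @param positions Sorted SNP base-pair positions of one chromosome.
#' @param chrom Chromosome label attached to the output.
#' @param region_size Window length in bp (default 1 Mb).
#' @param overlap_fraction Fraction of overlap between consecutive windows
#'   (default 0.5).
#' @param max_gap Maximum tolerated adjacent-SNP gap in bp (default 10 kb; a
#'   50 kb setting suits sparse arrays).
#' @param min_snps Minimum SNPs per retained window (default 64).
#' @return Tibble with columns `chrom`, `start`, `end`, `snp_count`,
#'   `max_gap_ok`; attribute `excluded_fraction` gives the dropped share of
#'   candidate windows.
#' @export
define_regions <- function(positions, chrom = "1", region_size = 1e6,
                           overlap_fraction = 0.5, max_gap = 1e4,
                           min_snps = 64) {
  positions <- sort(as.numeric(positions))
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), snp_count = integer(),
                          max_gap_ok = logical())
  if (!length(positions)) {
    attr(empty, "excluded_fraction") <- NA_real_
    return(empty)
  }
  step <- region_size * (1 - overlap_fraction)
  starts <- seq(1, max(positions), by = step)
  starts <- starts[starts + region_size - 1 <= max(positions)]
  if (!length(starts)) {
    attr(empty, "excluded_fraction") <- NA_real_
    return(empty)
  }
  spec <- purrr::map_dfr(starts, function(s) {
    e <- s + region_size - 1
    idx <- which(positions >= s & positions <= e)
    gaps_ok <- length(idx) >= 2 && max(diff(positions[idx])) <= max_gap
    tibble::tibble(chrom = as.character(chrom), start = s, end = e,
                   snp_count = length(idx),
                   max_gap_ok = gaps_ok)
  })
  keep <- spec$max_gap_ok & spec$snp_count >= min_snps
  out <- spec[keep, , drop = FALSE]
  attr(out, "excluded_fraction") <- 1 - mean(keep)
  out
}

#' Test one preprocessed region against the phenotype
#'
#' Runs the modelling half of the pipeline on a preprocessed coefficient
#' matrix: reverse regressions, constrained mixture fit, thresholded
#' posteriors, region summaries, composite statistic, and the calibrated
#' p-value.
#'
#' @param coefs A `"ws_coefs"` object from [ws_preprocess()].
#' @param design A `"ws_design"` from [build_design()].
#' @param calibration A `"ws_calibration"` from [ws_calibrate()].
#' @param k Mixture variance-constraint multiplier (default 100).
#' @return An object of class `"ws_result"`: `betas`, `fit`, `posteriors`
#'   (tibble), `Lh`, `ph`, `pv`, `minp`, `T`, `p_value`, `lambda`,
#'   region coordinates, `S`, `K`.
#' @export
ws_test_region <- function(coefs, design, calibration, k = 100) {
  stopifnot(inherits(coefs, "ws_coefs"), inherits(design, "ws_design"),
            inherits(calibration, "ws_calibration"))
  betas <- fit_coefficient_regressions(coefs, design)
  fit <- fit_constrained_mixture(betas, k = k)
  st <- region_statistics(betas, fit, K = design$K)
  T_stat <- compute_T(st$Lh, st$ph, st$pv, calibration$lambda_star)
  structure(
    list(betas = betas, fit = fit, posteriors = st$posteriors,
         Lh = st$Lh, ph = st$ph, pv = st$pv, minp = st$minp,
         T = T_stat, p_value = region_pvalue(T_stat, calibration),
         lambda = calibration$lambda_star,
         chrom = coefs$chrom, start = coefs$lb, end = coefs$ub,
         n_snps = coefs$n_snps, S = st$S, K = design$K),
    class = "ws_result"
  )
}

#' @export
print.ws_result <- function(x, ...) {
  cat(sprintf(
    "<ws_result> chr%s:%s-%s  L_h=%.4g p_h=%.3g p_v=%.3g T=%.4g p=%.3g\n",
    x$chrom, format(x$start, big.mark = ","), format(x$end, big.mark = ","),
    x$Lh, x$ph, x$pv, x$T, x$p_value))
  invisible(x)
}

#' Screen a set of regions genome-wide
#'
#' End-to-end per-region screening: for every window, preprocess the dosages
#' into quantile-normalised wavelet coefficients, reverse-regress on the
#' phenotype, fit the constrained mixture, assemble the composite statistic
#' and compute its calibrated p-value. Uses one shared analysis depth and one
#' null calibration (simulated here unless supplied), matching the
#' chromosome-wide design of the method.
#'
#' @param genotypes A `"ws_region"` holding all SNPs of the screened stretch,
#'   or a path to a VCF / dosage TSV readable by [read_genotypes()].
#' @param phenotype Numeric phenotype vector (one value per individual, in
#'   dosage-row order), or a tibble with columns `sample_id` and `value`
#'   matched against the dosage sample identifiers.
#' @param covariates Optional covariate matrix or tibble (with `sample_id`).
#' @param regions Optional window tibble from [define_regions()]; computed
#'   from the SNP positions when `NULL`.
#' @param S Analysis depth, or `"auto"` (depth rule on `region_size` and the
#'   median SNP spacing).
#' @param calibration Optional `"ws_calibration"`; simulated with
#'   `n_calib` random-signal draws when `NULL`.
#' @param n_calib Null draws used when calibrating here (default 10000).
#' @param k Mixture variance-constraint multiplier.
#' @param region_size,overlap_fraction,max_gap,min_snps Window parameters,
#'   see [define_regions()].
#' @param iq_min Imputation-quality filter when reading from a file.
#' @param seed RNG seed making the run deterministic.
#' @param out_prefix When non-`NULL`, writes `<prefix>.tsv` (the screen
#'   table) and `<prefix>_manifest.json` (run metadata).
#' @return Tibble with one row per region: coordinates, `snp_count`, `S`,
#'   `Lh`, `ph`, `pv`, `minp`, `T`, `p_value`, `pi_alt`, `converged`,
#'   `status` (`"ok"` or the failure reason; failed regions keep their row).
#' @export
ws_screen <- function(genotypes, phenotype, covariates = NULL,
                      regions = NULL, S = "auto", calibration = NULL,
                      n_calib = 10000, k = 100,
                      region_size = 1e6, overlap_fraction = 0.5,
                      max_gap = 1e4, min_snps = 64, iq_min = 0.8,
                      seed = NULL, out_prefix = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(genotypes)) {
    genotypes <- read_genotypes(genotypes, iq_min = iq_min)
  }
  stopifnot(inherits(genotypes, "ws_region"))
  K <- nrow(genotypes$dosages)

  phi <- match_phenotype(phenotype, genotypes)
  covariates <- match_covariates(covariates, genotypes)
  design <- build_design(phi, covariates)

  if (is.null(regions)) {
    regions <- define_regions(genotypes$positions, chrom = genotypes$chrom,
                              region_size = region_size,
                              overlap_fraction = overlap_fraction,
                              max_gap = max_gap, min_snps = min_snps)
  }
  if (!nrow(regions)) stop("no regions to screen", call. = FALSE)

  if (identical(S, "auto")) {
    spacing <- stats::median(diff(genotypes$positions))
    S <- choose_depth(region_size, spacing)$S
  }
  S <- as.integer(S)

  if (is.null(calibration)) {
    # calibrate on the first screenable window: permutation nulls reproduce
    # the exact randomness of the test (empirical correlation included)
    cal_coefs <- NULL
    for (r in seq_len(nrow(regions))) {
      cal_coefs <- tryCatch({
        idx <- which(genotypes$positions >= regions$start[r] &
                       genotypes$positions <= regions$end[r])
        reg <- genotype_region(genotypes$dosages[, idx, drop = FALSE],
                               genotypes$positions[idx],
                               iq = genotypes$iq[idx],
                               chrom = regions$chrom[r],
                               lb = regions$start[r], ub = regions$end[r])
        ws_preprocess(reg, S = S)
      }, error = function(e) NULL)
      if (!is.null(cal_coefs)) break
    }
    if (is.null(cal_coefs)) stop("no region could be preprocessed for calibration", call. = FALSE)
    calibration <- ws_calibrate(n_calib, S = S, v = design$v, K = K,
                                method = "permutation", coefs = cal_coefs,
                                phi = phi, k = k)
  }

  rows <- purrr::pmap(regions, function(chrom, start, end, ...) {
    res <- tryCatch({
      idx <- which(genotypes$positions >= start & genotypes$positions <= end)
      reg <- genotype_region(genotypes$dosages[, idx, drop = FALSE],
                             genotypes$positions[idx],
                             iq = genotypes$iq[idx],
                             chrom = chrom, lb = start, ub = end)
      coefs <- ws_preprocess(reg, S = S)
      ws_test_region(coefs, design, calibration, k = k)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      tibble::tibble(chrom = chrom, start = start, end = end,
                     snp_count = NA_integer_, S = S,
                     Lh = NA_real_, ph = NA_real_, pv = NA_real_,
                     minp = NA_real_, T = NA_real_, p_value = NA_real_,
                     pi_alt = NA_real_, converged = NA,
                     status = conditionMessage(res))
    } else {
      tibble::tibble(chrom = chrom, start = start, end = end,
                     snp_count = res$n_snps, S = res$S,
                     Lh = res$Lh, ph = res$ph, pv = res$pv,
                     minp = res$minp, T = res$T, p_value = res$p_value,
                     pi_alt = res$fit$pi_alt,
                     converged = isTRUE(res$fit$converged),
                     status = "ok")
    }
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$chrom, .data$start)
  failed <- sum(out$status != "ok")
  if (failed) {
    warning(failed, " region(s) failed and are flagged in `status`",
            call. = FALSE)
  }

  if (!is.null(out_prefix)) {
    utils::write.table(out, paste0(out_prefix, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- list(
      package = "wavescreen",
      version = as.character(utils::packageVersion("wavescreen")),
      seed = seed, S = S, K = K, k = k,
      lambda_star = calibration$lambda_star,
      null_mean = calibration$null_mean,
      null_sd = calibration$null_sd,
      n_calib = calibration$n_sims,
      regions = nrow(regions),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(manifest, paste0(out_prefix, "_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

match_phenotype <- function(phenotype, genotypes) {
  if (is.data.frame(phenotype)) {
    ids <- rownames(genotypes$dosages)
    if (is.null(ids)) {
      stop("dosage matrix has no sample identifiers to match the phenotype table",
           call. = FALSE)
    }
    m <- match(ids, phenotype$sample_id)
    if (anyNA(m)) stop("sample mismatch between genotypes and phenotype", call. = FALSE)
    as.numeric(phenotype$value[m])
  } else {
    phi <- as.numeric(phenotype)
    if (length(phi) != nrow(genotypes$dosages)) {
      stop("phenotype length must equal the number of individuals", call. = FALSE)
    }
    phi
  }
}

match_covariates <- function(covariates, genotypes) {
  if (is.null(covariates)) return(NULL)
  if (is.data.frame(covariates) && "sample_id" %in% names(covariates)) {
    ids <- rownames(genotypes$dosages)
    m <- match(ids, covariates$sample_id)
    if (anyNA(m)) stop("sample mismatch between genotypes and covariates", call. = FALSE)
    as.matrix(covariates[m, setdiff(names(covariates), "sample_id"), drop = FALSE])
  } else {
    as.matrix(covariates)
  }
}

#' Combine per-cohort region p-values with Fisher's method
#'
#' `chi2 = -2 sum(log p)` referred to a chi-square with `2 * length(p)`
#' degrees of freedom. With a single cohort this is the identity.
#'
#' @param p_values Vector of per-cohort p-values in `(0, 1]` for one region.
#' @return Tibble with `chi2`, `df`, `p_value`.
#' @examples
#' fisher_meta(c(0.05, 0.05))
#' @export
fisher_meta <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p) | p < 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  if (any(p == 0)) {
    warning("p-value of 0 clamped to the smallest positive double", call. = FALSE)
    p[p == 0] <- .Machine$double.xmin
  }
  chi2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  tibble::tibble(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Tidy table behind the pyramid display
#'
#' One row per (scale, location): the genomic span of the coefficient, the
#' estimated effect with its sign and magnitude, the posterior probabilities,
#' and whether the coefficient survives thresholding (the highlighted bars in
#' the pyramid display).
#'
#' @param result A `"ws_result"` from [ws_test_region()].
#' @return Tibble with columns `scale`, `loc`, `start`, `end`, `beta`,
#'   `sign`, `abs_beta`, `pi_hat`, `pi_tilde`, `highlighted`.
#' @export
export_plot_table <- function(result) {
  stopifnot(inherits(result, "ws_result"))
  L <- result$end - result$start + 1
  post <- result$posteriors
  tibble::tibble(
    scale = post$scale,
    loc = post$loc,
    start = result$start + (post$loc - 1) * 2^(-post$scale) * L,
    end = result$start + post$loc * 2^(-post$scale) * L,
    beta = post$beta,
    sign = sign(post$beta),
    abs_beta = abs(post$beta),
    pi_hat = post$pi_hat,
    pi_tilde = post$pi_tilde,
    highlighted = post$pi_tilde > 0
  )
}
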