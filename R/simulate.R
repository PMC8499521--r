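#' LD-block genotype model
#'
#' Parametric stand-in for a densely imputed 1 Mb locus: SNPs are partitioned
#' into contiguous LD blocks; within a block, latent Gaussian variables share
#' an exchangeable correlation `rho`, across blocks they are independent.
#' Latents are thresholded to 0/1/2 genotypes under Hardy-Weinberg at each
#' SNP's minor-allele frequency, and imputation noise with variance
#' `1 - IQ` is added before clipping to `[0, 2]`. The default emulates 28
#' LD blocks over 5209 SNPs at 202 bp spacing, imputation quality uniform on
#' `[0.8, 1]`, minor-allele frequencies uniform on `[0.05, 0.5]`.
#'
#' @param n_snps Number of SNPs.
#' @param n_blocks Number of LD blocks (contiguous, near-equal sizes).
#' @param rho Within-block latent correlation in `[0, 1)`.
#' @param maf_range Range of minor-allele frequencies.
#' @param spacing Base pairs between adjacent SNPs (uniform spacing).
#' @param iq_range Range of per-SNP imputation qualities.
#' @param start First SNP position.
#' @return A list of class `"ws_ld_model"`.
#' @export
ld_block_model <- function(n_snps = 5209, n_blocks = 28, rho = 0.8,
                           maf_range = c(0.05, 0.5), spacing = 202,
                           iq_range = c(0.8, 1), start = 1e6) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (any(maf_range <= 0) || any(maf_range > 0.5)) {
    stop("MAF range must lie in (0, 0.5]", call. = FALSE)
  }
  block <- sort(rep_len(seq_len(n_blocks), n_snps))
  structure(
    list(n_snps = n_snps, n_blocks = n_blocks, block = block, rho = rho,
         maf_range = maf_range, spacing = spacing, iq_range = iq_range,
         start = start),
    class = "ws_ld_model"
  )
}

#' Simulate an LD-structured genotype region
#'
#' Draws dosages from the latent Gaussian copula of [ld_block_model()]:
#' block-wise exchangeable latent correlation, Hardy-Weinberg thresholding to
#' 0/1/2, additive imputation noise of variance `1 - IQ`, clipped to
#' `[0, 2]`.
#'
#' @param K Number of individuals (>= 2).
#' @param model A `"ws_ld_model"`; default [ld_block_model()].
#' @param seed Optional RNG seed.
#' @return A `"ws_region"` with attributes `block` (per-SNP LD-block index)
#'   and `maf`.
#' @export
simulate_genotypes <- function(K, model = ld_block_model(), seed = NULL) {
  stopifnot(inherits(model, "ws_ld_model"), K >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- model$n_snps
  maf <- stats::runif(n, model$maf_range[1], model$maf_range[2])
  iq <- stats::runif(n, model$iq_range[1], model$iq_range[2])
  q1 <- stats::qnorm((1 - maf)^2)             # latent cut P(G = 0)
  q2 <- stats::qnorm(1 - maf^2)               # latent cut P(G <= 1)
  G <- matrix(0, K, n)
  sr <- sqrt(model$rho)
  se <- sqrt(1 - model$rho)
  for (b in seq_len(model$n_blocks)) {
    idx <- which(model$block == b)
    u <- stats::rnorm(K)
    z <- sr * u + se * matrix(stats::rnorm(K * length(idx)), K, length(idx))
    g0 <- (z > rep(q1[idx], each = K)) + (z > rep(q2[idx], each = K))
    noise <- matrix(stats::rnorm(K * length(idx)), K, length(idx)) *
      rep(sqrt(1 - iq[idx]), each = K)
    G[, idx] <- pmin(pmax(g0 + noise, 0), 2)
  }
  positions <- model$start + (seq_len(n) - 1) * model$spacing
  region <- genotype_region(G, positions, iq = iq, chrom = "sim",
                            lb = positions[1], ub = positions[n])
  attr(region, "block") <- model$block
  attr(region, "maf") <- maf
  region
}

#' Simulate a local-polygenic phenotype on a genotype region
#'
#' Builds a genetic score by summing (signed) dosages over a causal SNP set
#' and adds Gaussian noise so that the score explains `variance_explained` of
#' the total phenotypic variance. Under the mono-directional model (`"MD"`)
#' all causal effects are `+1`; under the random-direction model (`"RD"`)
#' signs are iid `+/-1`. `"high-LD"` selection draws causal SNPs from within
#' LD blocks with at least 5 members, at most one SNP per block until blocks
#' are exhausted; `"random-LD"` draws uniformly over all SNPs. With
#' `n_causal = 0` the phenotype is exactly standard normal (the pure null).
#'
#' @param region A `"ws_region"` from [simulate_genotypes()].
#' @param n_causal Number of causal SNPs (0 for the null).
#' @param model `"MD"` or `"RD"`.
#' @param causal_selection `"high-LD"` or `"random-LD"`.
#' @param variance_explained Fraction of phenotypic variance explained by the
#'   score (default 0.005).
#' @param seed Optional RNG seed.
#' @return List with `phi` (length-K phenotype), `causal` (SNP indices),
#'   `signs`, `achieved_ve` (realised score-variance fraction).
#' @export
simulate_phenotype <- function(region, n_causal,
                               model = c("MD", "RD"),
                               causal_selection = c("high-LD", "random-LD"),
                               variance_explained = 0.005, seed = NULL) {
  model <- match.arg(model)
  causal_selection <- match.arg(causal_selection)
  stopifnot(inherits(region, "ws_region"),
            variance_explained > 0, variance_explained < 1)
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(region$dosages)
  if (n_causal == 0) {
    return(list(phi = stats::rnorm(K), causal = integer(0),
                signs = integer(0), achieved_ve = 0))
  }
  for (attempt in 1:10) {
    causal <- draw_causal_set(region, n_causal, causal_selection)
    signs <- if (model == "MD") rep(1L, n_causal) else
      sample(c(-1L, 1L), n_causal, replace = TRUE)
    score <- as.numeric(region$dosages[, causal, drop = FALSE] %*% signs)
    if (stats::var(score) > 0) break
    if (attempt == 10) stop("causal score has zero variance", call. = FALSE)
  }
  vs <- stats::var(score)
  noise_var <- vs * (1 - variance_explained) / variance_explained
  phi <- score + stats::rnorm(K, sd = sqrt(noise_var))
  list(phi = phi, causal = causal, signs = signs,
       achieved_ve = vs / stats::var(phi))
}

# high-LD selection clusters causal SNPs: blocks with >= 5 members are opened
# in random order and each is filled with up to `per_block` causal SNPs
# before the next is opened, so causal SNPs are mutually correlated (the
# block-polygenic signature); random-LD draws uniformly over all SNPs
draw_causal_set <- function(region, n_causal, causal_selection,
                            per_block = 5L) {
  n <- ncol(region$dosages)
  if (causal_selection == "random-LD") {
    return(sample.int(n, n_causal))
  }
  block <- attr(region, "block")
  if (is.null(block)) stop("region has no LD-block annotation", call. = FALSE)
  sizes <- table(block)
  big <- as.integer(names(sizes)[sizes >= 5])
  if (!length(big)) stop("no LD block has >= 5 members", call. = FALSE)
  blocks_open <- sample(big)
  take <- rep(per_block, length(blocks_open))
  if (sum(take) < n_causal) stop("not enough eligible block SNPs", call. = FALSE)
  causal <- integer(0)
  for (b in blocks_open) {
    need <- n_causal - length(causal)
    if (need <= 0) break
    in_block <- which(block == b)
    causal <- c(causal, sample(in_block, min(per_block, need, length(in_block))))
  }
  causal
}

# batch modelling of one preprocessed region against many phenotype draws:
# per column of Phi, OLS slopes for all coefficients, mixture refit, and the
# L_h / p_h / p_v summaries (C++ inner loop)
batch_region_stats <- function(coefs, Phi, k = 100) {
  stopifnot(inherits(coefs, "ws_coefs"))
  G <- coefs$coef
  keep <- setdiff(seq_len(ncol(G)), coefs$excluded)
  wh <- scale_weights(coefs$scale)
  wv <- subregion_weights(coefs$S)$wv
  if (anyNA(wv)) wv <- wh
  thr <- pi_threshold(nrow(G), coefs$scale)
  Phi <- as.matrix(Phi)
  cphi <- scale(Phi, center = TRUE, scale = FALSE)
  ss <- colSums(cphi^2)
  if (any(ss <= 0)) stop("constant phenotype draw", call. = FALSE)
  W <- sweep(cphi, 2, ss, "/")
  B <- crossprod(W, G[, keep, drop = FALSE])   # replicates x coefficients
  res <- .em_batch_stats_cpp(B, v = 1 / ss, wh = wh[keep], wv = wv[keep],
                             thr = thr[keep], kfac = k)
  tibble::tibble(
    Lh = res[, "Lh"], ph = res[, "ph"], pv = res[, "pv"],
    minp = pmin(res[, "ph"], res[, "pv"]),
    pi_alt = res[, "pi_alt"], converged = res[, "converged"] > 0,
    v = 1 / ss
  )
}

#' Type-I error experiment
#'
#' Fixes one simulated genotype region, calibrates the composite statistic on
#' null draws, then repeatedly draws standard-normal phenotypes independent
#' of the genotypes, runs the full pipeline per replicate (regression,
#' mixture refit, summaries, p-value) and reports the empirical rejection
#' rate at each requested level with its Monte-Carlo standard error.
#'
#' @param K Sample size.
#' @param n_reps Number of null replicates.
#' @param alpha_levels Nominal significance levels.
#' @param model Genotype model, default [ld_block_model()].
#' @param region Optional pre-simulated `"ws_region"` (overrides `model`).
#' @param calibration Optional `"ws_calibration"` to reuse.
#' @param n_calib Null draws for calibration when computed here.
#' @param S Analysis depth (`NULL` = automatic depth rule).
#' @param k Mixture variance-constraint multiplier.
#' @param seed RNG seed.
#' @param chunk_size Replicates per batch.
#' @return Tibble with `alpha`, `rate`, `mc_se`, `n_reps`; the per-replicate
#'   p-values are attached as attribute `"p_values"` and the calibration as
#'   attribute `"calibration"`.
#' @export
run_type1_experiment <- function(K, n_reps, alpha_levels = c(0.05, 0.01),
                                 model = ld_block_model(), region = NULL,
                                 calibration = NULL, n_calib = 20000,
                                 S = NULL, k = 100, seed = NULL,
                                 chunk_size = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(region)) region <- simulate_genotypes(K, model)
  coefs <- ws_preprocess(region, S = S)
  if (is.null(calibration)) {
    calibration <- ws_calibrate(n_calib, S = coefs$S, v = 1 / (K - 1), K = K,
                                method = "permutation", coefs = coefs, k = k)
  }
  p_values <- numeric(n_reps)
  done <- 0L
  while (done < n_reps) {
    nb <- min(chunk_size, n_reps - done)
    Phi <- matrix(stats::rnorm(K * nb), K, nb)
    st <- batch_region_stats(coefs, Phi, k = k)
    T_stat <- compute_T(st$Lh, st$ph, st$pv, calibration$lambda_star)
    p_values[done + seq_len(nb)] <- region_pvalue(T_stat, calibration)
    done <- done + nb
  }
  out <- tibble::tibble(
    alpha = alpha_levels,
    rate = vapply(alpha_levels, function(a) mean(p_values <= a), numeric(1)),
    mc_se = sqrt(alpha_levels * (1 - alpha_levels) / n_reps),
    n_reps = n_reps
  )
  attr(out, "p_values") <- p_values
  attr(out, "calibration") <- calibration
  out
}

#' Power experiment over sample sizes and causal-set sizes
#'
#' For each sample size, one genotype region is simulated and calibrated;
#' each cell then repeatedly draws a causal set (uniformly within its
#' causal-count bin), simulates a local-polygenic phenotype at the requested
#' variance explained, runs the full pipeline, and reports the fraction of
#' replicates with region p-value at or below `significance`.
#'
#' @param K_grid Sample sizes.
#' @param models Phenotype effect models, subset of `c("MD", "RD")`.
#' @param causal_bins Named list of causal-count bins, e.g.
#'   `list("6-10" = 6:10)`.
#' @param n_reps Replicates per cell.
#' @param significance Per-test threshold (default 1e-5).
#' @param causal_selection `"high-LD"` or `"random-LD"`.
#' @param variance_explained Score variance fraction (default 0.005).
#' @param model Genotype model shared by all sample sizes.
#' @param n_calib,S,k,seed,chunk_size As in [run_type1_experiment()].
#' @return Tibble with `K`, `model`, `selection`, `bin`, `power`, `n_reps`.
#' @export
run_power_experiment <- function(K_grid, models = "MD",
                                 causal_bins = list("1" = 1, "6-10" = 6:10),
                                 n_reps = 500, significance = 1e-5,
                                 causal_selection = "high-LD",
                                 variance_explained = 0.005,
                                 model = ld_block_model(),
                                 n_calib = 20000, S = NULL, k = 100,
                                 seed = NULL, chunk_size = 500L) {
  if (!is.null(seed)) set.seed(seed)
  cells <- list()
  for (K in K_grid) {
    region <- simulate_genotypes(K, model)
    coefs <- ws_preprocess(region, S = S)
    calibration <- ws_calibrate(n_calib, S = coefs$S, v = 1 / (K - 1), K = K,
                                method = "permutation", coefs = coefs, k = k)
    for (eff in models) {
      for (bin_name in names(causal_bins)) {
        bin <- causal_bins[[bin_name]]
        p_values <- numeric(n_reps)
        done <- 0L
        while (done < n_reps) {
          nb <- min(chunk_size, n_reps - done)
          # phenotypes are standardised so the evidence statistic, whose
          # densities scale with the design variance factor, is compared to
          # the unit-variance-phenotype calibration
          Phi <- vapply(seq_len(nb), function(i) {
            nc <- if (length(bin) == 1L) bin else sample(bin, 1L)
            phi <- simulate_phenotype(region, nc, model = eff,
                                      causal_selection = causal_selection,
                                      variance_explained = variance_explained)$phi
            as.numeric(scale(phi))
          }, numeric(K))
          st <- batch_region_stats(coefs, Phi, k = k)
          T_stat <- compute_T(st$Lh, st$ph, st$pv, calibration$lambda_star)
          p_values[done + seq_len(nb)] <- region_pvalue(T_stat, calibration)
          done <- done + nb
        }
        cells[[length(cells) + 1L]] <- tibble::tibble(
          K = K, model = eff, selection = causal_selection, bin = bin_name,
          power = mean(p_values <= significance), n_reps = n_reps
        )
      }
    }
  }
  dplyr::bind_rows(cells)
}
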