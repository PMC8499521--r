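#' Per-coefficient scale weights
#'
#' Equal weight per scale: a coefficient at scale `s` receives weight
#' `1 / 2^s`, so every scale contributes the same total weight to the
#' horizontal summaries.
#'
#' @param scale Integer vector of coefficient scales.
#' @return Numeric weights.
#' @keywords internal
scale_weights <- function(scale) 2^(-scale)

#' Vertical sub-region membership weights
#'
#' The screened region is split into `S - 1` equal sub-regions along the
#' finest-scale axis, with boundaries `floor(2^S (k-1)/(S-1))` to
#' `floor(2^S k/(S-1))`. A coefficient (s, l) with `s >= 1` belongs to
#' sub-region `k` when its finest-scale footprint
#' `[(l-1) 2^(S-s) + 1, l 2^(S-s)]` overlaps that index range; `n_k` counts
#' the members. The vertical summary is then
#' `p_v = sum_k (1/n_k) sum_members pi_tilde`, i.e. a weighted sum with
#' per-coefficient weight `sum_k [member of k] / n_k`.
#'
#' @param S Maximum analysis depth (needs `S >= 2` for a proper split).
#' @return List with `wv` (per-coefficient weight vector, scale-major order,
#'   length `2^(S+1) - 1`), `n_k` (member counts) and `membership` (logical
#'   coefficients x sub-regions matrix).
#' @export
subregion_weights <- function(S) {
  S <- as.integer(S)
  scale <- c_scale_index(S)
  loc <- c_loc_index(S)
  M <- length(scale)
  if (S < 2L) {
    return(list(wv = rep(NA_real_, M), n_k = integer(0),
                membership = matrix(FALSE, M, 0)))
  }
  nk_regions <- S - 1L
  lo <- floor(2^S * (seq_len(nk_regions) - 1) / nk_regions)
  hi <- floor(2^S * seq_len(nk_regions) / nk_regions)
  lo <- pmax(lo, 1)
  fs <- (loc - 1) * 2^(S - scale) + 1
  fe <- loc * 2^(S - scale)
  membership <- matrix(FALSE, M, nk_regions)
  eligible <- scale >= 1L
  for (k in seq_len(nk_regions)) {
    membership[, k] <- eligible & fs <= hi[k] & fe >= lo[k]
  }
  n_k <- colSums(membership)
  wv <- as.numeric(membership %*% (1 / n_k))
  list(wv = wv, n_k = n_k, membership = membership)
}

#' Horizontal association summary
#'
#' `p_h = sum_s (1/2^s) sum_l pi_tilde[s, l]`: the average proportion of
#' alternative coefficients per scale, summed over scales, so `p_h <= S + 1`.
#'
#' @param pi_tilde Thresholded posteriors in scale-major order (length
#'   `2^(S+1) - 1`).
#' @param S Maximum depth.
#' @return Scalar `p_h`.
#' @export
compute_ph <- function(pi_tilde, S) {
  scale <- c_scale_index(S)
  stopifnot(length(pi_tilde) == length(scale))
  sum(scale_weights(scale) * pi_tilde)
}

#' Vertical association summary
#'
#' Average thresholded posterior within each of the `S - 1` vertical
#' sub-regions (scales 1..S only), summed over sub-regions, so
#' `p_v <= S - 1`. For `S < 2` there is no proper split and `p_v` falls back
#' to `p_h`.
#'
#' @inheritParams compute_ph
#' @return Scalar `p_v`.
#' @export
compute_pv <- function(pi_tilde, S) {
  if (S < 2L) return(compute_ph(pi_tilde, S))
  w <- subregion_weights(S)
  stopifnot(length(pi_tilde) == length(w$wv))
  sum(w$wv * pi_tilde)
}

#' Average evidence towards the alternative
#'
#' `L_h = sum_s (1/2^s) sum_l [ pi_tilde f_alt(beta) - (1 - pi_tilde)
#' f_null(beta) ]`, where `f_alt` and `f_null` are the fitted mixture
#' component densities. Each scale receives equal total weight. Excluded
#' (degenerate) coefficients contribute zero.
#'
#' @param beta Coefficient estimates in scale-major order (`NA` = excluded).
#' @param pi_tilde Thresholded posteriors, same order.
#' @param fit A `"ws_mixture"` fit.
#' @param S Maximum depth.
#' @return Scalar `L_h`.
#' @export
compute_Lh <- function(beta, pi_tilde, fit, S) {
  scale <- c_scale_index(S)
  stopifnot(length(beta) == length(scale), length(pi_tilde) == length(beta))
  ok <- !is.na(beta)
  f_alt <- stats::dnorm(beta[ok], fit$mu_alt, sqrt(fit$sigma2_alt))
  f_null <- stats::dnorm(beta[ok], 0, sqrt(fit$sigma2_null))
  sum(scale_weights(scale[ok]) *
        (pi_tilde[ok] * f_alt - (1 - pi_tilde[ok]) * f_null))
}

#' Composite region statistic
#'
#' `T = L_h + lambda * min(p_h, p_v)`.
#'
#' @param Lh,ph,pv Region summaries (vectorised).
#' @param lambda Non-negative inflation weight.
#' @return Numeric `T`.
#' @export
compute_T <- function(Lh, ph, pv, lambda) {
  stopifnot(all(lambda >= 0))
  Lh + lambda * pmin(ph, pv)
}

#' All region statistics for one fitted region
#'
#' Convenience wrapper: mixture posteriors, thresholding, and the `L_h`,
#' `p_h`, `p_v` summaries for an observed beta pyramid.
#'
#' @param betas A `"ws_betas"` object.
#' @param fit A `"ws_mixture"` fit for those betas.
#' @param K Sample size used for the posterior threshold.
#' @return List with `posteriors` (tibble incl. `pi_hat`, `pi_tilde`), `Lh`,
#'   `ph`, `pv`, `minp`, `S`.
#' @export
region_statistics <- function(betas, fit, K = betas$K) {
  stopifnot(inherits(betas, "ws_betas"), inherits(fit, "ws_mixture"))
  post <- threshold_posteriors(posterior_probabilities(betas, fit), K)
  S <- betas$S
  Lh <- compute_Lh(betas$beta, post$pi_tilde, fit, S)
  ph <- compute_ph(post$pi_tilde, S)
  pv <- compute_pv(post$pi_tilde, S)
  list(posteriors = post, Lh = Lh, ph = ph, pv = pv,
       minp = min(ph, pv), S = S)
}

# ---- null simulation ------------------------------------------------------

# returns a function(n) generating null beta draws for the chosen method;
# the closure returns list(betas = n x M matrix, v = scalar or per-draw vector)
null_beta_sampler <- function(method = c("permutation", "random-signal",
                                         "empirical-cov", "theoretical"),
                              S, v, coefs = NULL, cov = NULL, phi = NULL) {
  method <- match.arg(method)
  M <- 2^(S + 1L) - 1L
  if (method == "permutation") {
    if (is.null(coefs)) {
      stop("permutation nulls need the observed coefficient matrix", call. = FALSE)
    }
    mat <- if (inherits(coefs, "ws_coefs")) coefs$coef else as.matrix(coefs)
    if (ncol(mat) != M) stop("coefficient matrix does not match depth S", call. = FALSE)
    K <- nrow(mat)
    return(function(n) {
      Phi <- if (is.null(phi)) {
        matrix(stats::rnorm(K * n), K, n)
      } else {
        vapply(seq_len(n), function(i) sample(phi), numeric(K))
      }
      cphi <- scale(Phi, center = TRUE, scale = FALSE)
      ss <- colSums(cphi^2)
      W <- sweep(cphi, 2, ss, "/")
      list(betas = crossprod(W, mat), v = 1 / ss)
    })
  }
  if (method == "random-signal") {
    N <- 2^(S + 1L)
    return(function(n) {
      Z <- matrix(stats::rnorm(n * N), n, N)
      C <- c_pyramid_matrix(Z, S)
      C <- scale(C)          # exact column mean 0, variance 1
      list(betas = C * sqrt(v), v = v)
    })
  }
  R <- if (method == "empirical-cov") {
    if (is.null(cov)) {
      if (is.null(coefs)) {
        stop("empirical-cov needs a coefficient matrix or a covariance", call. = FALSE)
      }
      mat <- if (inherits(coefs, "ws_coefs")) coefs$coef else as.matrix(coefs)
      if (ncol(mat) != M) stop("coefficient matrix does not match depth S", call. = FALSE)
      cc <- suppressWarnings(stats::cor(mat))
      cc[!is.finite(cc)] <- 0
      diag(cc) <- 1
      cc
    } else {
      cv <- as.matrix(cov)
      stats::cov2cor(cv)
    }
  } else {
    P <- c_row_matrix(S + 1L, S)
    as.matrix(Matrix::tcrossprod(P))   # unit-norm rows: already a correlation
  }
  eig <- eigen(R, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(eig$values)) {
    warning("null beta covariance is not PSD; clipping negative eigenvalues",
            call. = FALSE)
  }
  ev <- pmax(eig$values, 0)
  A <- eig$vectors %*% (sqrt(ev) * t(eig$vectors))   # symmetric square root
  function(n) {
    Z <- matrix(stats::rnorm(n * M), n, M)
    list(betas = (Z %*% A) * sqrt(v), v = v)
  }
}

#' Simulate reverse-regression coefficients under the null
#'
#' The wavelet transform correlates the coefficient estimates, so null draws
#' must respect that correlation. Three interchangeable constructions are
#' offered: `"random-signal"` wavelet-transforms white-noise signals and
#' rescales columns to mean 0 / variance 1; `"empirical-cov"` draws from a
#' multivariate normal with the empirical column correlation of an observed
#' coefficient matrix (or a user-supplied covariance); `"theoretical"` uses
#' the exact row-overlap correlation of the sum-pyramid rows. All are scaled
#' so every marginal has variance `v`.
#'
#' @param n_sims Number of draws.
#' @param S Analysis depth.
#' @param v Design variance factor.
#' @param method One of `"permutation"` (reverse-regress fresh or permuted
#'   phenotypes on the observed coefficient matrix — the exact test null),
#'   `"random-signal"`, `"empirical-cov"`, `"theoretical"`.
#' @param coefs Coefficient matrix (or `"ws_coefs"`) for `"permutation"` /
#'   `"empirical-cov"`.
#' @param cov Optional explicit beta covariance for `"empirical-cov"`.
#' @param phi Observed phenotype to permute (`"permutation"` only; fresh
#'   standard-normal draws are used when `NULL`).
#' @param seed Optional RNG seed.
#' @return `n_sims` x `2^(S+1) - 1` matrix of null beta draws.
#' @export
simulate_null_betas <- function(n_sims, S, v,
                                method = c("random-signal", "permutation",
                                           "empirical-cov", "theoretical"),
                                coefs = NULL, cov = NULL, phi = NULL,
                                seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  sampler <- null_beta_sampler(method, S = S, v = v, coefs = coefs, cov = cov,
                               phi = phi)
  sampler(n_sims)$betas
}

#' Null distribution of the region summaries
#'
#' Draws null beta pyramids, refits the constrained mixture to every draw
#' (mirroring the full randomness of the observed statistic), and returns the
#' per-draw summaries `L_h`, `p_h`, `p_v` and `min(p_h, p_v)`. Computation is
#' chunked to bound memory.
#'
#' @inheritParams simulate_null_betas
#' @param K Sample size entering the posterior threshold.
#' @param k Mixture variance-constraint multiplier.
#' @param chunk_size Draws per chunk.
#' @return Tibble with columns `Lh`, `ph`, `pv`, `minp`, `pi_alt`,
#'   `converged`.
#' @export
ws_null_statistics <- function(n_sims, S, v, K,
                               method = c("random-signal", "permutation",
                                          "empirical-cov", "theoretical"),
                               coefs = NULL, cov = NULL, phi = NULL, k = 100,
                               seed = NULL, chunk_size = 5000L) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  sampler <- null_beta_sampler(method, S = S, v = v, coefs = coefs, cov = cov,
                               phi = phi)
  scale <- c_scale_index(S)
  wh <- scale_weights(scale)
  wv <- subregion_weights(S)$wv
  if (anyNA(wv)) wv <- wh   # S < 2: vertical summary degenerates to p_h
  thr <- pi_threshold(K, scale)
  # degenerate (excluded) observed columns carry no information and are
  # excluded from the mixture, mirroring the observed-statistic path
  keep <- seq_along(scale)
  if (method == "permutation" && inherits(coefs, "ws_coefs") &&
      length(coefs$excluded)) {
    keep <- setdiff(keep, coefs$excluded)
  }
  out <- vector("list", ceiling(n_sims / chunk_size))
  done <- 0L
  i <- 1L
  while (done < n_sims) {
    n <- min(chunk_size, n_sims - done)
    draw <- sampler(n)
    stats_mat <- .em_batch_stats_cpp(draw$betas[, keep, drop = FALSE],
                                     v = draw$v, wh = wh[keep], wv = wv[keep],
                                     thr = thr[keep], kfac = k)
    out[[i]] <- stats_mat
    done <- done + n
    i <- i + 1L
  }
  res <- do.call(rbind, out)
  tibble::tibble(
    Lh = res[, "Lh"], ph = res[, "ph"], pv = res[, "pv"],
    minp = pmin(res[, "ph"], res[, "pv"]),
    pi_alt = res[, "pi_alt"], converged = res[, "converged"] > 0
  )
}

# ---- lambda calibration ---------------------------------------------------

first_bin_stats <- function(p, bin_count = 1000L) {
  counts <- tabulate(pmin(floor(p * bin_count), bin_count - 1L) + 1L,
                     nbins = bin_count)
  c(count = counts[1L], rank = rank(-counts, ties.method = "min")[1L])
}

first_bin_rank <- function(p, bin_count = 1000L) {
  unname(first_bin_stats(p, bin_count)["rank"])
}

#' Calibrate the inflation hyperparameter lambda
#'
#' Balances power against null normality. A normal is fitted to the null
#' draws of `T_lambda = L_h + lambda * min(p_h, p_v)` and their p-values are
#' histogrammed into `bin_count` equal bins on `[0, 1]`; the first bin (p
#' near 0) is the one whose inflation would distort the false discovery
#' rate. Bins are ranked by descending count (rank 1 = fullest; ties share
#' the lowest rank). Scanning an increasing lambda grid, the search stops as
#' soon as the first bin becomes clearly more prominent than it was at
#' `lambda = 0`, and `lambda*` is the largest grid value at which the
#' first-bin prominence still equals the `lambda = 0` reference. Because the
#' rank readout also moves when unrelated bins reshuffle, "clearly more
#' prominent" and "equal" are judged on the first-bin count with Poisson
#' noise bands (`+3 sqrt(c)` to stop, `+1 sqrt(c)` for equality) alongside
#' the rank; both trajectories are returned. The null normal is then
#' refitted to `T_{lambda*}`.
#'
#' @param null_Lh,null_minp Vectors of null draws of `L_h` and
#'   `min(p_h, p_v)` (same length, ideally `>= 1e4`).
#' @param bin_count Number of histogram bins (default 1000).
#' @param lambda_grid Increasing grid of candidate lambdas; default geometric
#'   grid `sd(Lh)/sd(minp) * 2^j`, `j = -10..40`.
#' @param n_sims,method,seed Metadata recorded in the result.
#' @return An object of class `"ws_calibration"`: `lambda_star`,
#'   `null_mean`, `null_sd`, `first_bin_rank_ref`, `bin_count`,
#'   `lambda_grid`, `ranks`, `n_sims`, `method`, `seed`.
#' @export
calibrate_lambda <- function(null_Lh, null_minp, bin_count = 1000L,
                             lambda_grid = NULL, n_sims = length(null_Lh),
                             method = NA_character_, seed = NA_integer_) {
  stopifnot(length(null_Lh) == length(null_minp))
  if (length(null_Lh) < 1000) {
    warning("fewer than 1000 null draws; lambda calibration will be unstable",
            call. = FALSE)
  }
  if (is.null(lambda_grid)) {
    base <- stats::sd(null_Lh) / max(stats::sd(null_minp), 1e-12)
    lambda_grid <- base * 2^seq(-10, 40)
  }
  lambda_grid <- sort(unique(lambda_grid[lambda_grid >= 0]))

  stats_at <- function(lambda) {
    t_draws <- null_Lh + lambda * null_minp
    p <- stats::pnorm(t_draws, mean = mean(t_draws), sd = stats::sd(t_draws),
                      lower.tail = FALSE)
    first_bin_stats(p, bin_count)
  }
  ref <- stats_at(0)
  ref_rank <- unname(ref["rank"])
  ref_count <- unname(ref["count"])
  # the rank of the first bin is a noisy readout (unrelated bins reshuffle
  # as lambda moves); "rank increase observed" / "rank equal to reference"
  # are judged on the first-bin count with Poisson noise bands
  band_stop <- ref_count + 3 * sqrt(ref_count + 1)
  band_equal <- ref_count + sqrt(ref_count + 1)

  ranks <- integer(0)
  counts <- integer(0)
  stop_idx <- length(lambda_grid) + 1L
  for (j in seq_along(lambda_grid)) {
    st <- stats_at(lambda_grid[j])
    ranks[j] <- unname(st["rank"])
    counts[j] <- unname(st["count"])
    if (counts[j] > band_stop && ranks[j] < ref_rank) {  # clear inflation
      stop_idx <- j
      break
    }
  }
  scanned <- seq_len(min(stop_idx - 1L, length(ranks)))
  equal <- scanned[counts[scanned] <= band_equal]
  if (length(equal)) {
    lambda_star <- max(lambda_grid[equal])
  } else if (length(scanned)) {
    lambda_star <- max(lambda_grid[scanned])
  } else {
    lambda_star <- 0
    warning("first bin already inflated at the smallest lambda; lambda* = 0",
            call. = FALSE)
  }

  t_star <- null_Lh + lambda_star * null_minp
  structure(
    list(lambda_star = lambda_star,
         null_mean = mean(t_star),
         null_sd = stats::sd(t_star),
         first_bin_rank_ref = ref_rank,
         first_bin_count_ref = ref_count,
         bin_count = as.integer(bin_count),
         lambda_grid = lambda_grid[seq_along(ranks)],
         ranks = ranks,
         counts = counts,
         n_sims = n_sims,
         method = method,
         seed = seed),
    class = "ws_calibration"
  )
}

#' @export
print.ws_calibration <- function(x, ...) {
  cat(sprintf(
    "<ws_calibration> lambda* = %.6g, null T ~ N(%.4g, %.4g^2), %d sims (%s)\n",
    x$lambda_star, x$null_mean, x$null_sd, x$n_sims,
    if (is.na(x$method)) "method unknown" else x$method))
  invisible(x)
}

#' One-call null calibration for a region setting
#'
#' Simulates the null summaries with [ws_null_statistics()] and calibrates
#' lambda with [calibrate_lambda()].
#'
#' @inheritParams ws_null_statistics
#' @param bin_count,lambda_grid Passed to [calibrate_lambda()].
#' @return A `"ws_calibration"` object (with the null draws attached as
#'   attribute `"null_draws"`).
#' @export
ws_calibrate <- function(n_sims, S, v, K,
                         method = c("random-signal", "permutation",
                                    "empirical-cov", "theoretical"),
                         coefs = NULL, cov = NULL, phi = NULL, k = 100,
                         seed = NULL, bin_count = 1000L, lambda_grid = NULL,
                         chunk_size = 5000L) {
  method <- match.arg(method)
  draws <- ws_null_statistics(n_sims, S = S, v = v, K = K, method = method,
                              coefs = coefs, cov = cov, phi = phi, k = k,
                              seed = seed, chunk_size = chunk_size)
  cal <- calibrate_lambda(draws$Lh, draws$minp, bin_count = bin_count,
                          lambda_grid = lambda_grid, n_sims = n_sims,
                          method = method,
                          seed = if (is.null(seed)) NA_integer_ else seed)
  attr(cal, "null_draws") <- draws
  cal
}

#' Region p-value from the calibrated null
#'
#' Upper-tail probability of the composite statistic under the fitted null
#' normal: `p = 1 - Phi((T - null_mean) / null_sd)`.
#'
#' @param T Composite statistic value(s).
#' @param calibration A `"ws_calibration"` object.
#' @return p-value(s) in `(0, 1]`.
#' @export
region_pvalue <- function(T, calibration) {
  stopifnot(inherits(calibration, "ws_calibration"))
  stats::pnorm(T, mean = calibration$null_mean, sd = calibration$null_sd,
               lower.tail = FALSE)
}

#' Write / read a calibration as JSON
#'
#' Serialises the scalar calibration fields so that screening runs can reuse
#' a calibration without re-simulating.
#'
#' @param calibration A `"ws_calibration"` object.
#' @param path File path.
#' @return `read_calibration()` returns a `"ws_calibration"`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "ws_calibration"))
  fields <- calibration[c("lambda_star", "null_mean", "null_sd",
                          "first_bin_rank_ref", "bin_count", "n_sims",
                          "method", "seed")]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  fields <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields$lambda_grid <- numeric(0)
  fields$ranks <- integer(0)
  structure(fields, class = "ws_calibration")
}
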