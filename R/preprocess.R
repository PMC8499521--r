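#' Construct a genotype region
#'
#' Bundles the dosage matrix of one genomic window with its physical positions
#' and per-SNP imputation qualities. Dosages are expected-minor-allele counts
#' in `[0, 2]`; imputation quality (IQ) lies in `[0, 1]`, with 1 meaning a
#' genotyped or perfectly imputed SNP. The imputation noise variance at a SNP
#' is taken as `1 - IQ`.
#'
#' @param dosages Numeric matrix, individuals x SNPs, entries in `[0, 2]`
#'   (tolerance 1e-9).
#' @param positions Strictly increasing integer base-pair positions, one per
#'   SNP column.
#' @param iq Per-SNP imputation quality in `[0, 1]`; defaults to 1 (genotyped).
#' @param chrom Chromosome label.
#' @param lb,ub 1-based inclusive bounds of the window; default to the outer
#'   SNP positions.
#' @return An object of class `"ws_region"`: a list with elements `dosages`,
#'   `positions`, `iq`, `chrom`, `lb`, `ub`.
#' @export
genotype_region <- function(dosages, positions, iq = NULL, chrom = "1",
                            lb = NULL, ub = NULL) {
  dosages <- as.matrix(dosages)
  positions <- as.numeric(positions)
  n <- length(positions)
  if (ncol(dosages) != n) {
    stop("dosages must have one column per position", call. = FALSE)
  }
  if (n >= 2 && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(dosages))) {
    stop("dosages contain non-finite values", call. = FALSE)
  }
  if (any(dosages < -1e-9 | dosages > 2 + 1e-9)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  if (is.null(iq)) iq <- rep(1, n)
  if (length(iq) != n || any(iq < 0 | iq > 1)) {
    stop("iq must be one value per SNP in [0, 1]", call. = FALSE)
  }
  if (is.null(lb)) lb <- positions[1]
  if (is.null(ub)) ub <- positions[n]
  if (any(positions < lb | positions > ub)) {
    stop("positions must lie within [lb, ub]", call. = FALSE)
  }
  structure(
    list(dosages = dosages, positions = positions, iq = as.numeric(iq),
         chrom = as.character(chrom), lb = lb, ub = ub),
    class = "ws_region"
  )
}

#' @export
print.ws_region <- function(x, ...) {
  cat(sprintf("<ws_region> chr%s:%s-%s  %d individuals x %d SNPs\n",
              x$chrom, format(x$lb, big.mark = ","),
              format(x$ub, big.mark = ","),
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Map physical positions onto the unit interval
#'
#' Affine map sending the first SNP to 0 and the last to 1:
#' `x -> (x - bp_1) / (bp_n - bp_1)`.
#'
#' @param positions Strictly increasing numeric vector, length >= 2.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' map_positions(c(100, 150, 300))
#' @export
map_positions <- function(positions) {
  positions <- as.numeric(positions)
  n <- length(positions)
  if (n < 2) stop("need at least two positions", call. = FALSE)
  if (any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing (no duplicates)", call. = FALSE)
  }
  (positions - positions[1]) / (positions[n] - positions[1])
}

#' Number of dyadic grid points for n observations
#'
#' Returns `J = min{ j : 2^j >= n }`, the depth of the interpolation grid.
#'
#' @param n Number of SNPs.
#' @return Integer `J`.
#' @export
grid_depth <- function(n) {
  stopifnot(n >= 1)
  as.integer(ceiling(log2(n)))
}

#' Interpolate irregular genotype signals onto a dyadic grid
#'
#' Implements the gridding step for unevenly spaced data: each individual's
#' dosage signal is linearly interpolated onto the regular grid
#' `t_k = (k + 1/2) * 2^-J`, `k = 0..2^J - 1`, with `J = min{ j : 2^j >= n }`,
#' and constant extrapolation beyond the outermost SNPs. The sparse
#' interpolation map is retained so that per-SNP noise variances
#' (`1 - IQ`) can later be propagated through the interpolation weights and
#' the wavelet rows.
#'
#' @param positions01 Strictly increasing positions in `[0, 1]`.
#' @param values Numeric matrix (individuals x SNPs) of dosages.
#' @param snp_var Per-SNP noise variance proxy (default `0`, i.e. noiseless).
#' @return A list of class `"ws_grid"`: `grid` (the `t_k`), `values`
#'   (individuals x `2^J`), `J`, `interp` (sparse `2^J` x n map),
#'   `snp_var`, `grid_var` (diagonal-propagated per-grid-point variance).
#' @export
interpolate_to_grid <- function(positions01, values, snp_var = NULL) {
  values <- as.matrix(values)
  n <- length(positions01)
  if (n == 0) stop("no SNPs to interpolate", call. = FALSE)
  if (ncol(values) != n) stop("values must have one column per position", call. = FALSE)
  if (any(!is.finite(values))) stop("all-missing or non-finite dosages", call. = FALSE)
  if (any(diff(positions01) <= 0)) {
    stop("positions01 must be strictly increasing", call. = FALSE)
  }
  if (is.null(snp_var)) snp_var <- rep(0, n)
  if (any(snp_var < 0)) stop("negative snp_var", call. = FALSE)
  J <- grid_depth(n)
  N <- 2^J
  tk <- (seq_len(N) - 0.5) / N

  # bracketing SNP indices and linear weights (constant beyond the ends)
  right <- findInterval(tk, positions01) + 1L   # first SNP at or right of tk
  left <- pmax(right - 1L, 1L)
  right <- pmin(right, n)
  denom <- positions01[right] - positions01[left]
  w_right <- ifelse(denom > 0, (tk - positions01[left]) / denom, 0)
  w_right <- pmin(pmax(w_right, 0), 1)
  w_left <- 1 - w_right

  K <- nrow(values)
  gridded <- matrix(0, K, N)
  chunk <- 2048L
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    gridded[, idx] <-
      values[, left[idx], drop = FALSE] *
        matrix(w_left[idx], K, length(idx), byrow = TRUE) +
      values[, right[idx], drop = FALSE] *
        matrix(w_right[idx], K, length(idx), byrow = TRUE)
  }

  interp <- Matrix::sparseMatrix(
    i = c(seq_len(N), seq_len(N)),
    j = c(left, right),
    x = c(w_left, w_right),
    dims = c(N, n)
  )
  grid_var <- as.numeric((interp^2) %*% snp_var)

  structure(
    list(grid = tk, values = gridded, J = J, interp = interp,
         snp_var = as.numeric(snp_var), grid_var = grid_var),
    class = "ws_grid"
  )
}

# sparse matrix of normalised c-pyramid rows (M x N), scales 0..S of a
# length-2^J grid; row (s, l) has entries 2^(-(J-s)/2) over its support
c_row_matrix <- function(J, S) {
  N <- 2^J
  blocks <- lapply(0:S, function(s) {
    width <- 2^(J - s)
    Matrix::sparseMatrix(
      i = rep(seq_len(2^s), each = width),
      j = seq_len(N),
      x = 2^(-(J - s) / 2),
      dims = c(2^s, N)
    )
  })
  do.call(rbind, blocks)
}

#' Per-coefficient noise variances
#'
#' Propagates the diagonal per-SNP noise variance (`1 - IQ`) through the
#' linear interpolation weights and the orthonormal wavelet rows, giving the
#' noise variance of every sum-pyramid coefficient at scales `0..S`.
#'
#' @param gridded A `"ws_grid"` object from [interpolate_to_grid()].
#' @param S Maximum analysis depth.
#' @return Numeric vector of length `2^(S+1) - 1` in scale-major order.
#' @export
coefficient_variances <- function(gridded, S) {
  stopifnot(inherits(gridded, "ws_grid"), S <= gridded$J - 1L)
  rows <- c_row_matrix(gridded$J, S)
  snp_weights <- rows %*% gridded$interp     # M x n: net weight of each SNP
  as.numeric((snp_weights^2) %*% gridded$snp_var)
}

#' Coefficient-dependent wavelet shrinkage
#'
#' Universal-threshold shrinkage with a coefficient-specific threshold
#' `t = sqrt(2 log N) * sqrt(coeff_var)`, where `N` is the grid length. Soft
#' thresholding kills coefficients with `|x| <= t` and moves the rest toward
#' zero by `t`; hard thresholding only kills.
#'
#' @param coefs Numeric matrix (individuals x coefficients) of orthonormal
#'   pyramid coefficients, or a numeric vector for one individual.
#' @param coeff_var Non-negative per-coefficient noise variance.
#' @param n_grid Grid length `N` entering the universal threshold.
#' @param mode `"soft"` (default) or `"hard"`.
#' @return Shrunken coefficients, same shape as `coefs`.
#' @examples
#' visushrink(5, coeff_var = 1, n_grid = 1024)  # 5 - sqrt(2 log 1024)
#' @export
visushrink <- function(coefs, coeff_var, n_grid, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  if (any(coeff_var < 0)) stop("coeff_var must be non-negative", call. = FALSE)
  vec_in <- is.null(dim(coefs))
  coefs <- rbind(coefs)
  if (length(coeff_var) == 1L) coeff_var <- rep(coeff_var, ncol(coefs))
  thr <- sqrt(2 * log(n_grid)) * sqrt(coeff_var)
  thr_m <- matrix(thr, nrow(coefs), ncol(coefs), byrow = TRUE)
  out <- if (mode == "soft") {
    sign(coefs) * pmax(abs(coefs) - thr_m, 0)
  } else {
    coefs * (abs(coefs) > thr_m)
  }
  if (vec_in) unname(drop(out)) else out
}

#' Rank-based inverse-normal transform of coefficient columns
#'
#' Maps each column to normal scores via the Blom formula
#' `qnorm((rank - offset) / (K + 1 - 2 * offset))` with average ranks for
#' ties, so that every continuous column is marginally standard normal.
#' Constant (degenerate) columns cannot be Gaussianised — they behave as
#' discrete variables — and are flagged for exclusion from testing.
#'
#' @param x Numeric matrix (individuals x coefficients).
#' @param offset Rank offset; default Blom's 3/8.
#' @return List with `values` (transformed matrix; degenerate columns set to
#'   0) and `excluded` (integer indices of degenerate columns).
#' @examples
#' quantile_transform(cbind(c(10, 20, 30)))$values
#' @export
quantile_transform <- function(x, offset = 3 / 8) {
  x <- as.matrix(x)
  K <- nrow(x)
  if (K < 3) stop("need at least 3 individuals for the rank transform", call. = FALSE)
  rng <- matrixStats_colrange(x)
  excluded <- which(rng <= 0)
  out <- matrix(0, K, ncol(x), dimnames = dimnames(x))
  keep <- setdiff(seq_len(ncol(x)), excluded)
  if (length(keep)) {
    ranks <- apply(x[, keep, drop = FALSE], 2L, rank, ties.method = "average")
    out[, keep] <- stats::qnorm((ranks - offset) / (K + 1 - 2 * offset))
  }
  list(values = out, excluded = excluded)
}

matrixStats_colrange <- function(x) {
  apply(x, 2L, function(col) diff(range(col)))
}

#' Choose the analysis depth from SNP density
#'
#' Picks the deepest wavelet resolution that still leaves roughly
#' `target` SNPs per finest-scale coefficient: the largest `S` with
#' `region_len / (2^S * median_spacing) >= slack * target`. The default
#' slack of 0.85 resolves near-ties toward the deeper resolution, e.g. a
#' 1 Mb region at 202 bp median spacing yields `S = 9` (9.7 SNPs per
#' coefficient) and at 3525 bp yields `S = 5` (8.9).
#'
#' @param region_len Region length in base pairs.
#' @param median_spacing Median adjacent-SNP spacing in base pairs.
#' @param target Desired SNPs per finest-scale coefficient (default 10).
#' @param slack Acceptance fraction of the target (default 0.85).
#' @return A list with `S` (depth) and `snps_per_coeff` (achieved average).
#' @examples
#' choose_depth(1e6, 202)   # S = 9, about 9.7 SNPs per coefficient
#' choose_depth(1e6, 3525)  # S = 5, about 8.9
#' @export
choose_depth <- function(region_len, median_spacing, target = 10, slack = 0.85) {
  if (median_spacing <= 0) stop("median_spacing must be positive", call. = FALSE)
  avg <- function(S) region_len / (2^S * median_spacing)
  if (avg(1) < slack * target) {
    stop("no depth S >= 1 reaches ", slack * target,
         " SNPs per coefficient; enlarge the region or lower the target",
         call. = FALSE)
  }
  S <- 1L
  while (avg(S + 1L) >= slack * target) S <- S + 1L
  list(S = S, snps_per_coeff = avg(S))
}

#' Preprocess a genotype region into quantile-normalised wavelet coefficients
#'
#' Full pipeline: map positions to the unit interval, interpolate each
#' individual's dosages onto the dyadic grid, take the orthonormal sum-pyramid
#' coefficients at scales `0..S`, shrink them with coefficient-dependent
#' universal thresholds derived from the imputation noise (`1 - IQ`), and
#' quantile-transform each coefficient across the population to N(0, 1).
#'
#' @param region A `"ws_region"` from [genotype_region()] (or from
#'   [read_genotypes()]).
#' @param S Analysis depth; `NULL` (default) chooses it with [choose_depth()]
#'   from the region length and median SNP spacing, capped at `J - 1`.
#' @param threshold `"soft"`, `"hard"` or `"none"` shrinkage.
#' @param target_snps_per_coeff Target for the automatic depth rule.
#' @param inv_normal_offset Offset of the rank-based normal transform.
#' @return An object of class `"ws_coefs"`: list with `coef`
#'   (individuals x `2^(S+1)-1` quantile-normalised matrix, scale-major
#'   columns named `s<scale>_l<loc>`), `scale`, `loc`, `S`, `J`, `excluded`
#'   (degenerate column indices), `coeff_var`, and region metadata.
#' @export
ws_preprocess <- function(region, S = NULL,
                          threshold = c("soft", "hard", "none"),
                          target_snps_per_coeff = 10,
                          inv_normal_offset = 3 / 8) {
  stopifnot(inherits(region, "ws_region"))
  threshold <- match.arg(threshold)
  n <- length(region$positions)
  pos01 <- map_positions(region$positions)
  gridded <- interpolate_to_grid(pos01, region$dosages,
                                 snp_var = 1 - region$iq)
  J <- gridded$J
  if (is.null(S)) {
    spacing <- stats::median(diff(region$positions))
    S <- tryCatch(
      choose_depth(region$ub - region$lb + 1, spacing,
                   target = target_snps_per_coeff)$S,
      error = function(e) J - 1L
    )
    S <- min(S, J - 1L)
  }
  S <- as.integer(S)
  if (S < 1L || S > J - 1L) {
    stop("S must be in 1..J-1 (J = ", J, ")", call. = FALSE)
  }

  coefs <- c_pyramid_matrix(gridded$values, S)
  coeff_var <- coefficient_variances(gridded, S)
  if (threshold != "none") {
    coefs <- visushrink(coefs, coeff_var, n_grid = 2^J, mode = threshold)
  }
  qt <- quantile_transform(coefs, offset = inv_normal_offset)

  scale <- c_scale_index(S)
  loc <- c_loc_index(S)
  colnames(qt$values) <- paste0("s", scale, "_l", loc)

  structure(
    list(coef = qt$values, scale = scale, loc = loc, S = S, J = J,
         excluded = qt$excluded, coeff_var = coeff_var,
         chrom = region$chrom, lb = region$lb, ub = region$ub,
         n_snps = n, threshold = threshold),
    class = "ws_coefs"
  )
}

#' @export
print.ws_coefs <- function(x, ...) {
  cat(sprintf(
    "<ws_coefs> chr%s:%s-%s  %d individuals, depth S=%d (%d coefficients, %d excluded)\n",
    x$chrom, format(x$lb, big.mark = ","), format(x$ub, big.mark = ","),
    nrow(x$coef), x$S, ncol(x$coef), length(x$excluded)))
  invisible(x)
}
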