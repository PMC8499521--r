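#' Forward Haar wavelet transform of a dyadic-length signal
#'
#' Computes the Haar wavelet decomposition of a signal of length `2^J` by
#' Mallat's pyramid algorithm, either as the difference (`d`) spectrum or the
#' sum (`c`) pyramid.
#'
#' The `d` spectrum is the full orthogonal discrete wavelet transform: scale 0
#' holds the single approximation coefficient (the normalised overall sum) and
#' detail scale `s` (for `s >= 1`) holds `2^(s-1)` local differences, finest
#' differences at scale `J`. It has `2^J` coefficients in total, conserves
#' energy under the orthonormal convention, and is invertible with
#' [haar_inverse()].
#'
#' The `c` pyramid holds the local sums at every dyadic resolution: scale `s`
#' (for `s` in `0..J-1`) has `2^s` coefficients, each summarising a block of
#' `2^(J-s)` consecutive observations. With fully observed genotypes these are
#' local minor-allele counts (burden-style scores). The `c` pyramid is
#' redundant across scales and is the set of coefficients used for
#' association testing downstream.
#'
#' Differences are taken as (right half) minus (left half). Under the
#' `"orthonormal"` convention every transform row has unit norm; under
#' `"unnormalized"` coefficients are plain sums/differences, larger than the
#' orthonormal ones by `2^((J - s)/2)` for a row whose support has `2^(J-s)`
#' points (the sum-pyramid scale index `s`).
#'
#' @param x Numeric vector whose length is a power of two (at least 2), all
#'   values finite.
#' @param pyramid `"d"` for the orthogonal difference spectrum, `"c"` for the
#'   redundant sum pyramid.
#' @param convention `"orthonormal"` (unit-norm rows; default) or
#'   `"unnormalized"` (plain sums and differences).
#' @return A tibble with columns `scale`, `loc` (1-based location within the
#'   scale) and `coefficient`, ordered by scale then location, with attributes
#'   `J`, `pyramid` and `convention`. Class `"ws_spectrum"`.
#' @examples
#' haar_forward(c(2, 0, 0, 0))
#' haar_forward(c(1, 1, 1, 1), pyramid = "c", convention = "unnormalized")
#' @seealso [haar_inverse()]
#' @export
haar_forward <- function(x,
                         pyramid = c("d", "c"),
                         convention = c("orthonormal", "unnormalized")) {
  pyramid <- match.arg(pyramid)
  convention <- match.arg(convention)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L || !is_pow2(n)) {
    stop("signal length must be a power of two (>= 2), got ", n, call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("signal contains non-finite values", call. = FALSE)
  }
  J <- log2_int(n)

  if (pyramid == "d") {
    coef <- haar_dwt_vec(x)
    scale <- d_scale_index(J)
    loc <- d_loc_index(J)
    if (convention == "unnormalized") {
      # a detail row at spectrum scale s >= 1 has 2^(J-s+1) support points,
      # i.e. sum-pyramid index s - 1; the approximation row has index 0
      sum_s <- ifelse(scale == 0L, 0L, scale - 1L)
      coef <- coef * 2^((J - sum_s) / 2)
    }
  } else {
    coef <- drop(c_pyramid_matrix(matrix(x, nrow = 1L), S = J - 1L))
    scale <- c_scale_index(J - 1L)
    loc <- c_loc_index(J - 1L)
    if (convention == "unnormalized") {
      coef <- coef * 2^((J - scale) / 2)
    }
  }

  out <- tibble::tibble(scale = scale, loc = loc, coefficient = coef)
  attr(out, "J") <- J
  attr(out, "pyramid") <- pyramid
  attr(out, "convention") <- convention
  class(out) <- c("ws_spectrum", class(out))
  out
}

#' Inverse Haar wavelet transform
#'
#' Reconstructs the original signal from a complete orthonormal `d` spectrum
#' produced by [haar_forward()]. Round-trips are exact to numerical precision.
#'
#' @param spectrum A `ws_spectrum` tibble from
#'   `haar_forward(x, pyramid = "d", convention = "orthonormal")`.
#' @return Numeric vector of length `2^J`.
#' @examples
#' haar_inverse(haar_forward(c(2, 0, 0, 0)))
#' @export
haar_inverse <- function(spectrum) {
  J <- attr(spectrum, "J")
  if (is.null(J) || !identical(attr(spectrum, "pyramid"), "d") ||
      !identical(attr(spectrum, "convention"), "orthonormal")) {
    stop("haar_inverse() needs a complete orthonormal d spectrum from haar_forward()",
         call. = FALSE)
  }
  expect_scale <- d_scale_index(J)
  expect_loc <- d_loc_index(J)
  if (nrow(spectrum) != 2^J ||
      !identical(as.integer(spectrum$scale), expect_scale) ||
      !identical(as.integer(spectrum$loc), expect_loc)) {
    stop("incomplete or mis-ordered d spectrum", call. = FALSE)
  }
  coef <- spectrum$coefficient
  approx <- coef[1L]
  for (s in seq_len(J)) {
    d <- coef[spectrum$scale == s]
    left <- (approx - d) / sqrt(2)
    right <- (approx + d) / sqrt(2)
    approx <- as.vector(rbind(left, right))
  }
  approx
}

# ---- internal fast paths --------------------------------------------------

is_pow2 <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L

log2_int <- function(n) as.integer(round(log2(n)))

# full orthonormal Haar DWT of one vector; returns coefficients ordered
# scale 0 (approximation), then detail scales 1..J coarse-to-fine
haar_dwt_vec <- function(x) {
  J <- log2_int(length(x))
  details <- vector("list", J)
  a <- x
  for (s in rev(seq_len(J))) {
    odd <- a[seq(1L, length(a), by = 2L)]
    even <- a[seq(2L, length(a), by = 2L)]
    details[[s]] <- (even - odd) / sqrt(2)
    a <- (even + odd) / sqrt(2)
  }
  c(a, unlist(details))
}

d_scale_index <- function(J) {
  c(0L, unlist(lapply(seq_len(J), function(s) rep.int(s, 2^(s - 1L)))))
}

d_loc_index <- function(J) {
  c(1L, unlist(lapply(seq_len(J), function(s) seq_len(2^(s - 1L)))))
}

c_scale_index <- function(S) rep.int(0:S, 2^(0:S))

c_loc_index <- function(S) unlist(lapply(0:S, function(s) seq_len(2^s)))

# orthonormal c-pyramid coefficients for a K x 2^J matrix of signals,
# scales 0..S (S <= J-1): scale s column block holds the 2^s normalised
# block sums over windows of 2^(J-s) grid points
c_pyramid_matrix <- function(G, S) {
  n <- ncol(G)
  J <- log2_int(n)
  stopifnot(S <= J - 1L)
  K <- nrow(G)
  out <- matrix(0, K, 2^(S + 1L) - 1L)
  # block sums at the finest requested scale, then aggregate upwards
  width <- 2^(J - S)
  sums <- as.matrix(G %*% block_sum_indicator(n, width))
  col <- col_range_for_scale(S)
  out[, col] <- sums * 2^(-(J - S) / 2)
  if (S >= 1L) {
    for (s in (S - 1L):0L) {
      sums <- sums[, seq(1L, ncol(sums), by = 2L), drop = FALSE] +
        sums[, seq(2L, ncol(sums), by = 2L), drop = FALSE]
      out[, col_range_for_scale(s)] <- sums * 2^(-(J - s) / 2)
    }
  }
  out
}

col_range_for_scale <- function(s) (2^s):(2^(s + 1L) - 1L)

block_sum_indicator <- function(n, width) {
  m <- n %/% width
  Matrix::sparseMatrix(
    i = seq_len(n),
    j = rep(seq_len(m), each = width),
    x = 1,
    dims = c(n, m)
  )
}
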