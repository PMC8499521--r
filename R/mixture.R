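#' Fit the constrained two-component Gaussian mixture to the beta pyramid
#'
#' Models the collection of reverse-regression coefficients as
#' `(1 - pi_alt) N(0, sigma2_null) + pi_alt N(mu_alt, sigma2_alt)` and fits it
#' by EM with the null mean fixed at zero and the variance restrictions
#' `sigma2_null > v / 10` and `sigma2_alt > k * v`, where `v` is the design
#' variance factor of the phenotype coefficient. The restrictions keep the
#' components identifiable and force the estimated `pi_alt` to become small
#' when there is no signal. Constraints are enforced by clamping after each
#' M-step, which is the box-constrained M-step maximiser, so the EM ascent
#' property is retained.
#'
#' @param betas A `"ws_betas"` object from [fit_coefficient_regressions()],
#'   or a numeric vector of coefficients (then `v` is required).
#' @param v Design variance factor `(X'X)^{-1}[2,2]`; taken from `betas` when
#'   available.
#' @param k Alternative-variance constraint multiplier (default 100).
#' @param maxit,tol EM iteration cap and relative log-likelihood tolerance.
#' @return An object of class `"ws_mixture"`: `pi_alt`, `mu_alt`,
#'   `sigma2_null`, `sigma2_alt`, `loglik`, `trace` (log-likelihood per
#'   iteration), `converged`, `iterations`, `v`, `k`, `n_betas`.
#' @export
fit_constrained_mixture <- function(betas, v = NULL, k = 100,
                                    maxit = 500, tol = 1e-8) {
  if (inherits(betas, "ws_betas")) {
    if (is.null(v)) v <- betas$v
    beta <- betas$beta[!is.na(betas$beta)]
  } else {
    beta <- as.numeric(betas)
    beta <- beta[!is.na(beta)]
  }
  if (is.null(v) || v <= 0) stop("a positive variance factor v is required", call. = FALSE)
  if (length(beta) < 20) stop("need at least 20 usable beta values", call. = FALSE)
  fit <- .em_fit_cpp(beta, v = v, kfac = k, maxit = maxit, tol = tol)
  if (!fit$converged && length(fit$trace)) {
    warning("mixture EM did not converge in ", maxit,
            " iterations; returning best iterate", call. = FALSE)
  }
  structure(
    c(fit[c("pi_alt", "mu_alt", "sigma2_null", "sigma2_alt", "loglik",
            "trace", "converged", "iterations")],
      list(v = v, k = k, n_betas = length(beta))),
    class = "ws_mixture"
  )
}

#' @export
print.ws_mixture <- function(x, ...) {
  cat(sprintf(
    "<ws_mixture> pi_alt=%.4f, mu_alt=%.4g, sigma2_null=%.4g, sigma2_alt=%.4g (%s, %d iter)\n",
    x$pi_alt, x$mu_alt, x$sigma2_null, x$sigma2_alt,
    if (isTRUE(x$converged)) "converged" else "not converged", x$iterations))
  invisible(x)
}

#' Posterior probability of the alternative for each coefficient
#'
#' For every (scale, location) pair, the posterior probability that its
#' regression coefficient came from the alternative component:
#' `pi_hat = pi_alt f_alt(beta) / (pi_alt f_alt(beta) + (1 - pi_alt) f_null(beta))`,
#' computed in log space. Degenerate (excluded) coefficients get `pi_hat = 0`.
#'
#' @param betas A `"ws_betas"` object, or a numeric vector of coefficients.
#' @param fit A `"ws_mixture"` from [fit_constrained_mixture()].
#' @return A tibble with columns `scale`, `loc`, `beta`, `excluded`,
#'   `pi_hat`.
#' @export
posterior_probabilities <- function(betas, fit) {
  stopifnot(inherits(fit, "ws_mixture"))
  if (inherits(betas, "ws_betas")) {
    beta <- betas$beta
    scale <- betas$scale
    loc <- betas$loc
    excluded <- seq_along(beta) %in% betas$excluded
  } else {
    beta <- as.numeric(betas)
    S <- as.integer(round(log2(length(beta) + 1))) - 1L
    scale <- c_scale_index(S)
    loc <- c_loc_index(S)
    excluded <- is.na(beta)
  }
  pi_hat <- rep(0, length(beta))
  ok <- !excluded & !is.na(beta)
  if (fit$pi_alt >= 1) {
    pi_hat[ok] <- 1
  } else if (fit$pi_alt > 0) {
    la <- log(fit$pi_alt) +
      stats::dnorm(beta[ok], fit$mu_alt, sqrt(fit$sigma2_alt), log = TRUE)
    l0 <- log1p(-fit$pi_alt) +
      stats::dnorm(beta[ok], 0, sqrt(fit$sigma2_null), log = TRUE)
    mx <- pmax(la, l0)
    pi_hat[ok] <- exp(la - mx) / (exp(la - mx) + exp(l0 - mx))
  }
  tibble::tibble(scale = scale, loc = loc, beta = beta,
                 excluded = excluded, pi_hat = pi_hat)
}

#' Posterior threshold for a given sample size and scale
#'
#' The depth- and sample-size-dependent threshold
#' `1 / (sqrt(2 log K) * sqrt(2^s))` subtracted from the posterior
#' probabilities; it decreases with both the sample size `K` and the wavelet
#' scale `s` (natural logarithm).
#'
#' @param K Sample size (number of individuals).
#' @param s Wavelet scale (vectorised).
#' @return Numeric threshold(s).
#' @export
pi_threshold <- function(K, s) {
  stopifnot(K >= 2)
  1 / (sqrt(2 * log(K)) * sqrt(2^s))
}

#' Threshold posterior probabilities
#'
#' Applies `pi_tilde = max(pi_hat - 1 / (sqrt(2 log K) sqrt(2^s)), 0)` to
#' soften the influence of coefficients that most likely belong to the null.
#'
#' @param posteriors Tibble from [posterior_probabilities()] (columns `scale`
#'   and `pi_hat`).
#' @param K Sample size.
#' @return The input tibble with a `pi_tilde` column appended.
#' @export
threshold_posteriors <- function(posteriors, K) {
  stopifnot(is.data.frame(posteriors), all(c("scale", "pi_hat") %in% names(posteriors)))
  dplyr::mutate(posteriors,
                pi_tilde = pmax(.data$pi_hat - pi_threshold(K, .data$scale), 0))
}
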