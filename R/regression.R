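#' Build the reverse-regression design
#'
#' Assembles the design matrix `X = [1, phi, C]` used to regress every
#' quantile-normalised wavelet coefficient on the phenotype, and the variance
#' factor `v = (X'X)^{-1}[2,2]` of the phenotype coefficient under unit
#' residual variance. The phenotype may be continuous, a count, or binary
#' coded 0/1; it always enters as a predictor (reverse regression).
#'
#' @param phi Numeric phenotype vector, length K.
#' @param covariates Optional numeric matrix/data frame of covariates (K x c).
#' @return A list of class `"ws_design"`: `X`, `v`, `qr` (QR factorisation of
#'   `X`, shared by all per-coefficient fits), `K`.
#' @examples
#' build_design(c(1, 2, 3, 4))$v  # 1 / sum((phi - mean(phi))^2) = 0.2
#' @export
build_design <- function(phi, covariates = NULL) {
  phi <- as.numeric(phi)
  K <- length(phi)
  if (any(!is.finite(phi))) stop("phenotype contains non-finite values", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, phi = phi)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != K) stop("covariate rows must match phenotype length", call. = FALSE)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("C", seq_len(ncol(covariates)))
    }
    X <- cbind(X, covariates)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  v <- solve(crossprod(X))[2, 2]
  structure(list(X = X, v = v, qr = qr_x, K = K), class = "ws_design")
}

#' Fit all per-coefficient reverse regressions
#'
#' Ordinary least squares of every coefficient column on `[1, phi, C]`,
#' computed through one shared QR factorisation of the design. Only the
#' phenotype coefficient is retained. Residual variance is not re-estimated
#' per column: quantile transformation fixes it at 1, so each estimate has
#' null variance `v` exactly.
#'
#' @param coefs A `"ws_coefs"` object from [ws_preprocess()], or a plain
#'   numeric matrix of quantile-normalised coefficient columns.
#' @param design A `"ws_design"` from [build_design()].
#' @return A list of class `"ws_betas"`: `beta` (named vector, degenerate
#'   columns `NA`), `scale`, `loc`, `excluded`, `v`, `S`, `K`.
#' @export
fit_coefficient_regressions <- function(coefs, design) {
  stopifnot(inherits(design, "ws_design"))
  if (inherits(coefs, "ws_coefs")) {
    mat <- coefs$coef
    scale <- coefs$scale
    loc <- coefs$loc
    excluded <- coefs$excluded
    S <- coefs$S
  } else {
    mat <- as.matrix(coefs)
    S <- as.integer(round(log2(ncol(mat) + 1))) - 1L
    scale <- c_scale_index(S)
    loc <- c_loc_index(S)
    excluded <- integer(0)
  }
  if (nrow(mat) != design$K) stop("coefficient rows must match design rows", call. = FALSE)
  if (design$K <= ncol(design$X)) stop("need K > number of design columns", call. = FALSE)
  all_coef <- qr.coef(design$qr, mat)
  beta <- all_coef[2L, ]
  if (length(excluded)) beta[excluded] <- NA_real_
  names(beta) <- colnames(mat)
  structure(
    list(beta = beta, scale = scale, loc = loc, excluded = excluded,
         v = design$v, S = S, K = design$K),
    class = "ws_betas"
  )
}

#' @export
print.ws_betas <- function(x, ...) {
  cat(sprintf("<ws_betas> depth S=%d, %d coefficients (%d excluded), v=%.3g\n",
              x$S, length(x$beta), length(x$excluded), x$v))
  invisible(x)
}
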