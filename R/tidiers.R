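#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a constrained mixture fit
#'
#' One row per mixture component with its weight, mean and variance.
#'
#' @param x A `"ws_mixture"` object.
#' @param ... Unused.
#' @return Tibble with columns `component`, `weight`, `mean`, `variance`.
#' @export
tidy.ws_mixture <- function(x, ...) {
  tibble::tibble(
    component = c("null", "alternative"),
    weight = c(1 - x$pi_alt, x$pi_alt),
    mean = c(0, x$mu_alt),
    variance = c(x$sigma2_null, x$sigma2_alt)
  )
}

#' @rdname tidy.ws_mixture
#' @return `glance()` returns a one-row tibble with the fit summary.
#' @export
glance.ws_mixture <- function(x, ...) {
  tibble::tibble(
    pi_alt = x$pi_alt, mu_alt = x$mu_alt,
    sigma2_null = x$sigma2_null, sigma2_alt = x$sigma2_alt,
    loglik = x$loglik, iterations = x$iterations,
    converged = isTRUE(x$converged), n_betas = x$n_betas, v = x$v
  )
}

#' Tidy a region test result
#'
#' The coefficient-level table behind the pyramid display (one row per
#' scale/location pair); see [export_plot_table()].
#'
#' @param x A `"ws_result"` object.
#' @param ... Unused.
#' @return Tibble, one row per wavelet coefficient.
#' @export
tidy.ws_result <- function(x, ...) export_plot_table(x)

#' @rdname tidy.ws_result
#' @return `glance()` returns a one-row tibble with the region statistics.
#' @export
glance.ws_result <- function(x, ...) {
  tibble::tibble(
    chrom = x$chrom, start = x$start, end = x$end, n_snps = x$n_snps,
    S = x$S, K = x$K, Lh = x$Lh, ph = x$ph, pv = x$pv, minp = x$minp,
    lambda = x$lambda, T = x$T, p_value = x$p_value,
    pi_alt = x$fit$pi_alt
  )
}

#' Tidy a null calibration
#'
#' @param x A `"ws_calibration"` object.
#' @param ... Unused.
#' @return `tidy()` returns the scanned lambda grid with the first-bin rank
#'   at each value; `glance()` a one-row summary.
#' @export
tidy.ws_calibration <- function(x, ...) {
  tibble::tibble(lambda = x$lambda_grid, first_bin_rank = x$ranks)
}

#' @rdname tidy.ws_calibration
#' @export
glance.ws_calibration <- function(x, ...) {
  tibble::tibble(
    lambda_star = x$lambda_star, null_mean = x$null_mean,
    null_sd = x$null_sd, first_bin_rank_ref = x$first_bin_rank_ref,
    n_sims = x$n_sims, method = x$method
  )
}

#' Pyramid display of a region result
#'
#' Classic pyramidal wavelet layout: one dot per coefficient at its genomic
#' midpoint, dot size proportional to the absolute effect estimate, colour
#' its sign (blue negative, red positive); coefficients whose posterior
#' survives thresholding are highlighted by a shaded vertical band spanning
#' their genomic footprint.
#'
#' @param object A `"ws_result"` from [ws_test_region()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ws_result <- function(object, ...) {
  tab <- export_plot_table(object)
  tab$mid <- (tab$start + tab$end) / 2
  highlighted <- tab[tab$highlighted, , drop = FALSE]
  gg <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$mid, y = .data$scale))
  if (nrow(highlighted)) {
    gg <- gg + ggplot2::geom_rect(
      data = highlighted,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = .data$scale - 0.45, ymax = .data$scale + 0.45),
      inherit.aes = FALSE, fill = "goldenrod", alpha = 0.35
    )
  }
  gg +
    ggplot2::geom_point(ggplot2::aes(size = .data$abs_beta,
                                     colour = factor(.data$sign))) +
    ggplot2::scale_colour_manual(
      values = c(`-1` = "steelblue", `0` = "grey60", `1` = "firebrick"),
      name = "sign of β̂"
    ) +
    ggplot2::scale_y_reverse(breaks = 0:object$S) +
    ggplot2::scale_size_area(name = "|β̂|", max_size = 4) +
    ggplot2::labs(
      x = sprintf("position on chr%s (bp)", object$chrom),
      y = "wavelet scale (0 = coarsest)",
      title = sprintf("chr%s:%s-%s  p = %.2g", object$chrom,
                      format(object$start, big.mark = ","),
                      format(object$end, big.mark = ","), object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Manhattan-style overview of a screen table
#'
#' @param screen_table Tibble from [ws_screen()].
#' @param significance Horizontal reference line (default 1e-5).
#' @return A ggplot object.
#' @export
plot_screen <- function(screen_table, significance = 1e-5) {
  ok <- screen_table[screen_table$status == "ok", , drop = FALSE]
  ggplot2::ggplot(ok, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = -log10(.data$p_value))) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_hline(yintercept = -log10(significance),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "region midpoint (bp)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
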