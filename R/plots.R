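#' Scatter of clonotype count pairs
#'
#' The standard replicate/time-point diagnostic: unique count pairs on
#' double-log axes, point size by multiplicity. If `calls` (output of
#' [detect_responding()]) is supplied, points are colored by call.
#'
#' @param tab A [pair_table()].
#' @param calls Optional tibble from [detect_responding()].
#' @return A ggplot object.
#' @export
plot_count_pairs <- function(tab, calls = NULL) {
  stopifnot(inherits(tab, "pair_table"))
  df <- pt_pairs(tab)
  df$x <- df$n + 0.5          # offset so zero counts are visible on log axes
  df$y <- df$n_prime + 0.5
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(calls)) {
    key <- dplyr::distinct(calls, .data$n, .data$n_prime, .data$call)
    df <- dplyr::left_join(df, key, by = c("n", "n_prime"))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          color = .data$call)) +
      ggplot2::scale_color_manual(values = c(
        expanded = "#c0392b", contracted = "#2e6da4", unresolved = "grey55"
      ))
  }
  p +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), alpha = 0.6) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "count n (sample 1) + 0.5", y = "count n' (sample 2) + 0.5",
                  size = "clones") +
    ggplot2::theme_minimal()
}

#' Plot a fitted null model against the data
#'
#' Marginal count distribution \eqn{P(n)} of the fitted model (line)
#' overlaid on the empirical count histogram of both samples (points), on
#' double-log axes; the model should reproduce the power-law tail inherited
#' from the clone-size distribution and the noise-dominated low-count bend.
#'
#' @param object A `null_fit`.
#' @param tab The [pair_table()] the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.null_fit <- function(object, tab, ...) {
  stopifnot(inherits(tab, "pair_table"))
  cnt <- c(tab$n, tab$n_prime)
  cnt <- cnt[cnt > 0]
  emp <- dplyr::count(tibble::tibble(n = cnt), .data$n, name = "k")
  # conditional P(n | n > 0) under the fit, averaged over the two depths
  ns <- sort(unique(emp$n))
  pm <- marginal_count_pmf(c(0L, ns), object$prior, object$model, object$n_read)
  p0 <- pm$prob[1]
  mod <- tibble::tibble(n = ns, p = pm$prob[-1] / (1 - p0))
  ggplot2::ggplot() +
    ggplot2::geom_point(data = emp,
                        ggplot2::aes(x = .data$n, y = .data$k / sum(.data$k)),
                        alpha = 0.5) +
    ggplot2::geom_line(data = mod, ggplot2::aes(x = .data$n, y = .data$p),
                       color = "#c0392b") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "molecule count n", y = "P(n | n > 0)") +
    ggplot2::theme_minimal()
}

#' Plot the expansion likelihood surface
#'
#' The \eqn{(\alpha, \bar s)} grid-search surface on log axes with the
#' optimum marked: the characteristic diagonal ridge means the product
#' \eqn{\alpha\bar s} is well determined while the factors trade off.
#'
#' @param object An `expansion_fit`.
#' @param drop Contour floor: per-clone average log-likelihood values more
#'   than `drop` below the maximum are clipped before plotting
#'   (default 0.01).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expansion_fit <- function(object, drop = 0.01, ...) {
  surf <- object$surface
  mx <- max(surf$log_likelihood, na.rm = TRUE)
  surf$ll <- pmax(surf$log_likelihood, mx - drop)
  ggplot2::ggplot(surf, ggplot2::aes(x = .data$alpha, y = .data$sbar)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$ll)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$ll), color = "grey30",
                          bins = 8) +
    ggplot2::annotate("point", x = object$alpha, y = object$sbar,
                      shape = 4, size = 3, stroke = 1.2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "responding fraction alpha", y = "effect size sbar",
                  fill = "avg log-lik") +
    ggplot2::theme_minimal()
}

#' Plot a posterior over the log fold-change
#'
#' Continuous posterior density with the non-responding \eqn{\delta}-atom
#' drawn as a vertical segment at \eqn{s_0} (its height is the atom
#' weight divided by the lattice step, i.e. the density of an
#' atom smeared over one cell — labeled separately).
#'
#' @param object A `posterior_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.posterior_grid <- function(object, ...) {
  df <- tibble::tibble(s = object$s, density = object$density)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::annotate("segment", x = object$atom_s, xend = object$atom_s,
                      y = 0, yend = object$atom_weight / object$h,
                      color = "#c0392b", linewidth = 1.1) +
    ggplot2::labs(x = "log fold-change s",
                  y = "posterior density (atom in red)") +
    ggplot2::theme_minimal()
}
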