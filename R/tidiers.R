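#' Tidy a null-model fit
#'
#' One row per parameter with its estimate and projected-Hessian standard
#' error (on the optimization scales: \eqn{\nu, a, \gamma} linear,
#' \eqn{M} and \eqn{f_{\min}} as \eqn{\log_{10}}).
#'
#' @param x A `null_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.null_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$theta),
    estimate = as.numeric(x$theta),
    std.error = if (is.null(x$errors)) NA_real_ else as.numeric(x$errors)
  )
}

#' Glance at a null-model fit
#'
#' @param x A `null_fit`.
#' @param ... Unused.
#' @return A one-row tibble: noise kind, normalization mode, average
#'   conditioned log-likelihood, observed and estimated total clone
#'   numbers, \eqn{P(0,0)}, realized normalization `Z`, convergence code.
#' @export
glance.null_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, normalization = x$normalization,
    log_likelihood = x$log_likelihood, n_obs = x$n_obs,
    N = x$N, P00 = x$P00, Z = x$Z, convergence = x$convergence
  )
}

#' Tidy an expansion-model fit
#'
#' Estimates on natural scales; standard errors for `alpha` and `sbar` are
#' delta-method transforms of the log-scale covariance.
#'
#' @param x An `expansion_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.expansion_fit <- function(x, ...) {
  se <- c(NA_real_, NA_real_)
  if (!is.null(x$covariance)) {
    sd_log10 <- sqrt(pmax(diag(x$covariance), 0))
    se <- c(x$alpha, x$sbar) * log(10) * sd_log10
  }
  out <- tibble::tibble(
    term = c("alpha", "sbar", "s0"),
    estimate = c(x$alpha, x$sbar, x$s0),
    std.error = c(se, NA_real_)
  )
  if (x$family == "gauss_offcentered") {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "s1", estimate = x$s1, std.error = NA_real_
    ))
  }
  out
}

#' Glance at an expansion-model fit
#'
#' @param x An `expansion_fit`.
#' @param ... Unused.
#' @return A one-row tibble: family, estimates, average conditioned
#'   log-likelihood, number of observed clones, convergence code.
#' @export
glance.expansion_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, alpha = x$alpha, sbar = x$sbar, s0 = x$s0,
    log_likelihood = x$log_likelihood, n_obs = x$n_obs,
    convergence = x$convergence
  )
}
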