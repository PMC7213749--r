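#' Measurement noise models for repertoire sequencing counts
#'
#' Defines the conditional law \eqn{P(n \mid f)} of the observed molecule
#' (UMI) count \eqn{n} of a clonotype given its true frequency \eqn{f} in the
#' repertoire, in one of three variants:
#'
#' * `"poisson"` — pure sampling noise: \eqn{n \sim} Poisson with mean
#'   \eqn{f N_{\mathrm{read}}}.
#' * `"negbin"` — over-dispersed counts: negative binomial with mean
#'   \eqn{\bar n = f N_{\mathrm{read}}} and variance
#'   \eqn{\bar n + a \bar n^{\gamma}}; reduces to Poisson when \eqn{a = 0}.
#' * `"negbin_poisson"` — two-step law through a latent cell count \eqn{m}:
#'   \eqn{m \sim} negative binomial with mean \eqn{\bar m = f M} and variance
#'   \eqn{\bar m + a \bar m^{\gamma}} (cell sampling plus expression noise),
#'   then \eqn{n \mid m \sim} Poisson with mean
#'   \eqn{m N_{\mathrm{read}}/M = m\varepsilon} (mRNA capture), where
#'   \eqn{M} is the effective number of cells in the sample and
#'   \eqn{\varepsilon = N_{\mathrm{read}}/M} the sequencing efficiency
#'   (UMIs per cell).
#'
#' The over-dispersion parameters are clonotype-independent; the noise is a
#' property of the protocol, learned once from same-day replicates.
#'
#' @param kind One of `"poisson"`, `"negbin"`, `"negbin_poisson"`.
#' @param a Over-dispersion coefficient (\eqn{\ge 0}); ignored for `"poisson"`.
#' @param gamma Over-dispersion exponent; ignored for `"poisson"`.
#' @param M Effective number of cells in the sample (`"negbin_poisson"` only).
#' @return An object of class `noise_model`.
#' @examples
#' noise_model("poisson")
#' noise_model("negbin", a = 0.7, gamma = 1.1)
#' noise_model("negbin_poisson", a = 0.7, gamma = 1.1, M = 1e6)
#' @export
noise_model <- function(kind = c("poisson", "negbin", "negbin_poisson"),
                        a = 0, gamma = 2, M = NULL) {
  kind <- match.arg(kind)
  if (kind != "poisson") {
    if (!is.numeric(a) || length(a) != 1L || a < 0) {
      rlang::abort("`a` must be a single number >= 0 (variance below the mean is not a valid over-dispersion).")
    }
    if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma)) {
      rlang::abort("`gamma` must be a single finite number.")
    }
  }
  if (kind == "negbin_poisson") {
    if (is.null(M) || !is.numeric(M) || length(M) != 1L || M <= 0) {
      rlang::abort("`M` (effective cell number, > 0) is required for the two-step model.")
    }
  }
  structure(list(kind = kind, a = a, gamma = gamma, M = M), class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "<noise_model>  kind = %s%s%s\n", x$kind,
    if (x$kind != "poisson") sprintf(", a = %.4g, gamma = %.4g", x$a, x$gamma) else "",
    if (x$kind == "negbin_poisson") sprintf(", M = %.4g", x$M) else ""
  ))
  invisible(x)
}

# negative-binomial size parameter from the mean-variance relation
# var = mu + a mu^gamma  =>  size = mu^2/(var - mu) = mu^(2-gamma)/a
nb_size <- function(mu, a, gamma) mu^(2 - gamma) / a

# continuous-in-m negative binomial density (Gamma-function form), log scale
dnbinom_cont_log <- function(m, size, mu) {
  q <- size / (size + mu)  # success prob
  lgamma(m + size) - lgamma(size) - lgamma(m + 1) + size * log(q) + m * log1p(-q)
}

#' Zero-count probability
#'
#' Closed-form \eqn{P(0 \mid f)} for all three noise kinds. For the
#' negative binomial it is the pmf at zero; for the two-step law it is the
#' negative-binomial probability generating function evaluated at
#' \eqn{z = e^{-\varepsilon}}:
#' \eqn{P(0\mid f) = \left(1 + \bar m (1 - e^{-\varepsilon})/r\right)^{-r}}
#' with \eqn{\bar m = fM} and \eqn{r} the NB size, which tends to the
#' Poisson-mixture limit \eqn{e^{-\bar m(1 - e^{-\varepsilon})}} as
#' \eqn{a \to 0}. Exact and vectorized; used wherever only the unseen-clone
#' probability is needed.
#'
#' @param model A [noise_model()].
#' @param f Vector of frequencies.
#' @param n_read Total molecule count of the sample.
#' @return \eqn{P(0 \mid f)}, same length as `f`.
#' @export
noise_zero_prob <- function(model, f, n_read) {
  stopifnot(inherits(model, "noise_model"))
  switch(model$kind,
    poisson = exp(-f * n_read),
    negbin = {
      mu <- f * n_read
      if (model$a == 0) return(exp(-mu))
      r <- nb_size(mu, model$a, model$gamma)
      exp(-r * log1p(mu / r))
    },
    negbin_poisson = {
      eps <- n_read / model$M
      mb <- f * model$M
      q <- -expm1(-eps)
      if (model$a == 0) return(exp(-mb * q))
      r <- nb_size(mb, model$a, model$gamma)
      exp(-r * log1p(mb * q / r))
    }
  )
}

# cell-count pmf/quantiles for the two-step model; Poisson cell counts in
# the a = 0 limit
cell_pmf <- function(m, mb, model) {
  if (model$a == 0) stats::dpois(m, mb)
  else stats::dnbinom(m, size = nb_size(mb, model$a, model$gamma), mu = mb)
}
cell_quantile <- function(p, mb, model, lower.tail = TRUE) {
  if (model$a == 0) stats::qpois(p, mb, lower.tail = lower.tail)
  else stats::qnbinom(p, size = nb_size(mb, model$a, model$gamma), mu = mb,
                      lower.tail = lower.tail)
}
cell_dens_log <- function(m, mb, model) {
  if (model$a == 0) m * log(mb) - mb - lgamma(m + 1)
  else dnbinom_cont_log(m, nb_size(mb, model$a, model$gamma), mb)
}

# Poisson log-pmf on a grid of means, via one outer product:
# K[j, k] = exp(n_k * log(lam_j) - lam_j - lgamma(n_k + 1))
pois_kernel <- function(lam, n, lgam_n = lgamma(n + 1)) {
  K <- outer(log(lam), n)
  K <- K - lam                       # column recycling over rows
  K <- sweep(K, 2L, lgam_n, "-")
  exp(K)
}

#' Count pmf matrix over a frequency grid
#'
#' Evaluates \eqn{P(n \mid f)} for every combination of the supplied
#' frequencies and counts. This is the computational core shared by all
#' likelihoods: evaluations are vectorized over the unique counts, never per
#' clone. For the two-step model the latent cell count is marginalized by an
#' exact sum over integers for small mean cell counts and by Gauss-Legendre
#' quadrature against the continuous negative-binomial density for large
#' ones.
#'
#' @param model A [noise_model()].
#' @param f Vector of frequencies in (0, 1).
#' @param n Vector of non-negative integer counts.
#' @param n_read Total molecule (UMI) count of the sample.
#' @param m_switch Mean cell count below which the two-step sum over
#'   \eqn{m} is exact (default 40).
#' @param m_nodes Number of trapezoid nodes for the continuous-\eqn{m}
#'   branch (default 100; the integrand is smooth and concentrated, where
#'   the uniform trapezoid rule is spectrally accurate).
#' @param allow_extended Permit `f > 1`; used internally when evaluating
#'   the count law at shifted frequencies \eqn{f e^s} in the expansion
#'   model, where the formal argument of \eqn{P(n \mid \cdot)} can exceed 1.
#' @return A `length(f)` by `length(n)` matrix of probabilities.
#' @export
count_pmf_matrix <- function(model, f, n, n_read, m_switch = 40, m_nodes = 100,
                             allow_extended = FALSE) {
  stopifnot(inherits(model, "noise_model"))
  if (any(f <= 0) || (!allow_extended && any(f > 1))) {
    rlang::abort("`f` must lie in (0, 1].")
  }
  if (any(n < 0) || any(n != floor(n))) rlang::abort("`n` must be non-negative integers.")
  if (length(n_read) != 1L || n_read < 1) rlang::abort("`n_read` must be a single count >= 1.")
  nf <- length(f); nn <- length(n)

  if (model$kind == "poisson" || (model$kind == "negbin" && model$a == 0)) {
    mu <- f * n_read
    return(matrix(stats::dpois(rep(n, each = nf), rep(mu, nn)), nf, nn))
  }

  if (model$kind == "negbin") {
    mu <- f * n_read
    size <- nb_size(mu, model$a, model$gamma)
    return(matrix(
      stats::dnbinom(rep(n, each = nf), size = rep(size, nn), mu = rep(mu, nn)),
      nf, nn
    ))
  }

  # two-step: P(n|f) = sum_m P(m|f) Pois(n; m eps), with P(m|f) negative
  # binomial (Poisson in the a = 0 limit; the compound stays over-dispersed
  # relative to Poisson reads because the cell count is latent)
  eps <- n_read / model$M
  mbar <- f * model$M
  out <- matrix(0, nf, nn)
  ord <- order(n)
  ns <- n[ord]
  lgam_ns <- lgamma(ns + 1)
  vtot <- mbar * eps + eps^2 * (mbar + model$a * mbar^model$gamma)
  for (i in seq_len(nf)) {
    mb <- mbar[i]
    # active count window: counts outside +-12 sd of the mean carry
    # ~Gaussian-tail mass (< 1e-12 relative) and are left at 0
    nb_i <- mb * eps
    sd_i <- sqrt(vtot[i])
    k1 <- findInterval(nb_i - 12 * sd_i - 10, ns) + 1L
    k2 <- findInterval(nb_i + 12 * sd_i + 30, ns)
    if (k2 < k1) next
    act <- k1:k2
    if (mb <= m_switch) {
      m_top <- max(cell_quantile(1e-13, mb, model, lower.tail = FALSE), 8)
      m <- 0:m_top
      wm <- cell_pmf(m, mb, model)
      K <- pois_kernel(pmax(m * eps, 1e-300), ns[act], lgam_ns[act])
      if (ns[act][1] == 0) K[, 1] <- exp(-m * eps)  # avoid 0*log(0) at lam ~ 0
      out[i, ord[act]] <- as.numeric(crossprod(wm, K))
    } else {
      lo <- cell_quantile(1e-13, mb, model)
      hi <- cell_quantile(1e-13, mb, model, lower.tail = FALSE)
      m <- seq(max(lo, 1e-6), hi, length.out = m_nodes)
      hm <- m[2] - m[1]
      wm <- hm * exp(cell_dens_log(m, mb, model))
      wm[c(1, m_nodes)] <- wm[c(1, m_nodes)] / 2
      K <- pois_kernel(m * eps, ns[act], lgam_ns[act])
      out[i, ord[act]] <- as.numeric(crossprod(wm, K))
    }
  }
  out
}

#' Count pmf
#'
#' \eqn{P(n \mid f)} for a single frequency, vectorized over counts.
#' See [count_pmf_matrix()] for the model definitions.
#'
#' @param n Vector of non-negative integer counts.
#' @param f Single frequency in (0, 1).
#' @param model A [noise_model()].
#' @param n_read Total molecule count of the sample.
#' @param ... Passed to [count_pmf_matrix()].
#' @return Vector of probabilities, one per `n`.
#' @examples
#' count_pmf(0, 1e-5, noise_model("poisson"), n_read = 1e6)  # exp(-10)
#' @export
count_pmf <- function(n, f, model, n_read, ...) {
  as.numeric(count_pmf_matrix(model, f, n, n_read, ...))
}

#' Mean and variance of the count law
#'
#' Moment relations of \eqn{P(n\mid f)}: Poisson has variance equal to the
#' mean \eqn{\bar n = f N_{\mathrm{read}}}; the negative binomial has
#' variance \eqn{\bar n + a\bar n^\gamma}; the two-step law has, by the law
#' of total variance,
#' \deqn{\mathrm{Var}(n) = \bar n + \varepsilon^2\left(\bar m +
#'   a \bar m^\gamma\right), \qquad \bar m = f M,\;
#'   \varepsilon = N_{\mathrm{read}}/M.}
#'
#' @param model A [noise_model()].
#' @param f Vector of frequencies.
#' @param n_read Total molecule count of the sample.
#' @return A [tibble::tibble()] with columns `f`, `mean`, `variance`.
#' @export
pmf_mean_variance <- function(model, f, n_read) {
  stopifnot(inherits(model, "noise_model"))
  nbar <- f * n_read
  v <- switch(model$kind,
    poisson = nbar,
    negbin = nbar + model$a * nbar^model$gamma,
    negbin_poisson = {
      eps <- n_read / model$M
      mbar <- f * model$M
      nbar + eps^2 * (mbar + model$a * mbar^model$gamma)
    }
  )
  tibble::tibble(f = f, mean = nbar, variance = v)
}

#' Marginal count distribution
#'
#' The count distribution marginalized over the clone-size prior,
#' \eqn{P(n) = \int \rho(f) P(n \mid f)\, df}, evaluated on the package's
#' logarithmic frequency grid. For Poisson noise and large \eqn{n},
#' \eqn{P(n)} inherits the power law of \eqn{\rho(f)},
#' \eqn{P(n) \propto n^{-\nu}}.
#'
#' @param n Vector of counts.
#' @param prior A [clone_size_prior()].
#' @param model A [noise_model()].
#' @param n_read Total molecule count of the sample.
#' @param grid Optional precomputed [frequency_grid()].
#' @return A tibble with columns `n` and `prob`.
#' @export
marginal_count_pmf <- function(n, prior, model, n_read, grid = NULL) {
  if (is.null(grid)) grid <- frequency_grid(prior)
  A <- count_pmf_matrix(model, grid$f, n, n_read)
  cq <- grid$cq / sum(grid$cq)   # discretized prior, proper on the grid
  tibble::tibble(n = n, prob = as.numeric(crossprod(cq, A)))
}

#' Draw counts from the noise model
#'
#' Samples one count per frequency from \eqn{P(n \mid f)}; the generative
#' counterpart of [count_pmf()]. For the two-step model the latent cell
#' count is sampled explicitly and then thinned.
#'
#' @param f Vector of frequencies.
#' @param model A [noise_model()].
#' @param n_read Total molecule count of the sample.
#' @return Integer-valued vector of counts, same length as `f`.
#' @export
sample_counts <- function(f, model, n_read) {
  stopifnot(inherits(model, "noise_model"))
  k <- length(f)
  switch(model$kind,
    poisson = stats::rpois(k, f * n_read),
    negbin = {
      if (model$a == 0) return(stats::rpois(k, f * n_read))
      mu <- f * n_read
      stats::rnbinom(k, size = nb_size(mu, model$a, model$gamma), mu = mu)
    },
    negbin_poisson = {
      eps <- n_read / model$M
      mbar <- f * model$M
      m <- if (model$a == 0) stats::rpois(k, mbar) else
        stats::rnbinom(k, size = nb_size(mbar, model$a, model$gamma), mu = mbar)
      stats::rpois(k, m * eps)
    }
  )
}
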