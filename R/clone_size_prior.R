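#' Power-law prior over clone frequencies
#'
#' Constructs the prior density over clone frequencies
#' \deqn{\rho(f) = C f^{-\nu}, \quad f_{\min} \le f < 1,}
#' the standard parametrization of lymphocyte clone-size distributions
#' (a power law with exponent \eqn{\nu > 1} and a lower cutoff
#' \eqn{f_{\min}} reflecting the smallest possible clonal frequency).
#' The normalization constant \eqn{C} is computed in closed form and cached.
#'
#' Either supply `f_min` directly, or supply the total number of clones `N`
#' in the organism, in which case `f_min` is solved from the mean-frequency
#' constraint \eqn{N \langle f \rangle = 1} (see [solve_fmin()]), which
#' ensures that clone frequencies sum to one on average.
#'
#' @param nu Power-law exponent \eqn{\nu}; must exceed 1 (the normalization
#'   diverges otherwise).
#' @param f_min Lower frequency cutoff in (0, 1). Ignored when `N` is given.
#' @param N Total number of clones in the organism; used to derive `f_min`
#'   from \eqn{N\langle f\rangle = 1} when `f_min` is `NULL`.
#'
#' @return An object of class `clone_size_prior`: a list with fields `nu`,
#'   `f_min`, `C` (normalization constant) and, when derived from `N`, `N`.
#' @examples
#' pr <- clone_size_prior(nu = 2, f_min = 1e-6)
#' pr$C                         # ~1.000001e-6
#' clone_moment(1, pr)          # mean frequency
#' pr2 <- clone_size_prior(nu = 2, N = 1e6)
#' pr2$f_min                    # ~6.0e-8
#' @export
clone_size_prior <- function(nu, f_min = NULL, N = NULL) {
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 1) {
    rlang::abort("`nu` must be a single finite number > 1 (normalization diverges for nu <= 1).")
  }
  if (is.null(f_min)) {
    if (is.null(N)) rlang::abort("Supply either `f_min` or `N`.")
    f_min <- solve_fmin(nu, N)
  }
  if (!is.numeric(f_min) || length(f_min) != 1L || f_min <= 0 || f_min >= 1) {
    rlang::abort("`f_min` must lie strictly inside (0, 1).")
  }
  C <- (nu - 1) / (f_min^(1 - nu) - 1)
  structure(
    list(nu = nu, f_min = f_min, C = C, N = if (!is.null(N)) N else NULL),
    class = "clone_size_prior"
  )
}

#' @export
print.clone_size_prior <- function(x, ...) {
  cat(sprintf(
    "<clone_size_prior>  nu = %.4g, f_min = %.4g, C = %.4g%s\n",
    x$nu, x$f_min, x$C,
    if (!is.null(x$N)) sprintf(", N = %.4g (N<f> = 1)", x$N) else ""
  ))
  invisible(x)
}

#' Clone-frequency density
#'
#' Evaluates \eqn{\rho(f) = C f^{-\nu}} on its support
#' \eqn{[f_{\min}, 1)}; returns 0 outside the support.
#'
#' @param f Vector of frequencies.
#' @param prior A [clone_size_prior()].
#' @return Density values, same length as `f`.
#' @export
clone_density <- function(f, prior) {
  stopifnot(inherits(prior, "clone_size_prior"))
  out <- ifelse(f >= prior$f_min & f < 1, prior$C * f^(-prior$nu), 0)
  as.numeric(out)
}

#' Moments of the clone-frequency prior
#'
#' Closed-form \eqn{\langle f^\beta\rangle = C\,(1 - f_{\min}^{\,\beta-\nu+1})
#' /(\beta-\nu+1)}, with the logarithmic special case
#' \eqn{\beta - \nu + 1 = 0} (where the integral is
#' \eqn{C\ln(1/f_{\min})}) handled exactly.
#'
#' @param beta Moment order (vectorized; any real \eqn{\ge 0}).
#' @param prior A [clone_size_prior()].
#' @return \eqn{\langle f^\beta \rangle} for each `beta`.
#' @export
clone_moment <- function(beta, prior) {
  stopifnot(inherits(prior, "clone_size_prior"))
  p <- beta - prior$nu + 1
  lfm <- log(prior$f_min)
  # expm1 keeps precision when p*log(f_min) is small
  vapply(p, function(pi) {
    if (abs(pi * lfm) < 1e-8) {
      # integral of f^(p-1) ~ log branch (exact at p = 0)
      prior$C * (-lfm) * (1 - pi * lfm / 2)
    } else {
      prior$C * (-expm1(pi * lfm)) / pi
    }
  }, numeric(1))
}

# <-f log f> under rho(f), the Shannon-entropy integrand needed for D_1
clone_neg_flogf <- function(prior) {
  p <- 2 - prior$nu
  lfm <- log(prior$f_min)
  if (abs(p) < 1e-8) {
    # nu = 2: integral of f^(-1) (-log f) df = (log f_min)^2 / 2
    prior$C * lfm^2 / 2
  } else {
    fp <- exp(p * lfm)
    prior$C * ((1 - fp) / p^2 + fp * lfm / p)
  }
}

#' Solve the minimum frequency from the normalization constraint
#'
#' Finds the unique \eqn{f_{\min} \in (0,1)} satisfying
#' \eqn{N \langle f \rangle_{\rho(f)} = 1}: with `N` clones whose frequencies
#' are drawn independently from the prior, the expected total frequency is
#' one, so the power law is consistent with frequencies summing to 1.
#'
#' @param nu Power-law exponent (> 1).
#' @param N Total number of clones (> 1).
#' @param tol Relative tolerance on the root (default 1e-12).
#' @return The solved `f_min`.
#' @examples
#' solve_fmin(2, 1e6)   # ~6.0e-8
#' @export
solve_fmin <- function(nu, N, tol = 1e-12) {
  stopifnot(is.numeric(nu), nu > 1, is.numeric(N), N > 1)
  g <- function(x) N * clone_moment(1, clone_size_prior(nu, f_min = exp(x))) - 1
  lo <- -700
  hi <- log(1 - 1e-12)
  if (g(lo) >= 0 || g(hi) <= 0) {
    rlang::abort("No root for f_min in (0, 1): check `nu` and `N`.")
  }
  r <- stats::uniroot(g, lower = lo, upper = hi, tol = tol)
  exp(r$root)
}

#' Hill diversities of the repertoire
#'
#' Hill numbers of order \eqn{\beta} under the factorized clone-frequency
#' prior with `N` clones:
#' \deqn{D_\beta = \left(N\langle f^\beta\rangle\right)^{1/(1-\beta)},}
#' with \eqn{D_0 = N} (species richness),
#' \eqn{D_1 = \exp\!\big(N\langle -f\ln f\rangle\big)} (exponential Shannon
#' entropy, the \eqn{\beta \to 1} limit) and
#' \eqn{D_2 = 1/(N\langle f^2\rangle)} (inverse Simpson index).
#'
#' @param beta Vector of orders \eqn{\ge 0}.
#' @param prior A [clone_size_prior()].
#' @param N Total number of clones; defaults to the `N` stored in `prior`.
#' @return A numeric vector of diversities, one per `beta`.
#' @export
hill_diversity <- function(beta, prior, N = prior$N) {
  stopifnot(inherits(prior, "clone_size_prior"))
  if (is.null(N)) rlang::abort("Supply `N` (not stored in this prior).")
  if (any(beta < 0)) rlang::abort("`beta` must be >= 0.")
  vapply(beta, function(b) {
    if (b == 0) return(N)
    if (abs(b - 1) < 1e-9) return(exp(N * clone_neg_flogf(prior)))
    (N * clone_moment(b, prior))^(1 / (1 - b))
  }, numeric(1))
}

#' Logarithmic frequency grid
#'
#' Builds the quadrature grid used by all frequency integrals in the
#' package: nodes uniformly spaced in \eqn{\ln f} over
#' \eqn{[f_{\min}, 1)}, with trapezoidal weights in \eqn{\ln f}. The
#' density spans many decades, so log spacing controls relative error
#' uniformly. The grid step also serves as the lattice unit for
#' log-fold-change shifts in the expansion model (shifting \eqn{f} by
#' \eqn{e^{s}} is an integer translation of the grid when \eqn{s} is a
#' lattice multiple).
#'
#' The grid is anchored at the upper end: nodes sit on the fixed lattice
#' \eqn{\ln f = -k\,h}, \eqn{k = 0, 1, \dots}, with one extra node exactly
#' at \eqn{\ln f_{\min}} closing a partial bottom cell (non-uniform
#' trapezoid weight). Anchoring keeps the node positions fixed as
#' \eqn{f_{\min}} varies, so likelihoods are smooth functions of the
#' parameters (required for finite-difference Hessians).
#'
#' @param prior A [clone_size_prior()].
#' @param step Lattice spacing \eqn{h} in \eqn{\ln f} (default 0.05).
#' @return A list with `f` (nodes, ascending), `lnf`, `h`, `n_lattice`
#'   (number of on-lattice nodes), `wq` (trapezoid quadrature weights for
#'   \eqn{\int \cdot\, df}), and `cq` (\eqn{\rho(f)}-weighted weights,
#'   summing to ~1).
#' @export
frequency_grid <- function(prior, step = 0.05) {
  stopifnot(inherits(prior, "clone_size_prior"))
  lmin <- log(prior$f_min)
  K <- as.integer(ceiling(-lmin / step - 1e-9))     # lattice nodes: -(K-1)h .. 0
  lat <- (-(K - 1):0) * step
  if (lat[1] - lmin > 1e-12) {
    lnf <- c(lmin, lat)
    off_lattice <- TRUE
  } else {
    lnf <- lat
    off_lattice <- FALSE
  }
  n <- length(lnf)
  f <- exp(lnf)
  # non-uniform trapezoid weights in ln f
  d <- diff(lnf)
  tw <- c(d[1] / 2, (d[-1] + d[-length(d)]) / 2, d[length(d)] / 2)
  wq <- f * tw                    # int g(f) df = int g(f) f dln f
  cq <- wq * clone_density(f, prior)
  list(f = f, lnf = lnf, h = step, n_lattice = K,
       off_lattice = off_lattice, wq = wq, cq = cq)
}
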