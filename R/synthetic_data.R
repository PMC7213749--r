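#' Simulation configuration
#'
#' Bundles the generative model for synthetic repertoire experiments: the
#' repertoire size `N`, the clone-size power law (`nu`, with `f_min` derived
#' from the mean constraint \eqn{N\langle f\rangle = 1}), the noise model,
#' per-sample read totals, and (optionally) an expansion prior for
#' two-time-point simulations.
#'
#' For the two-step noise model the read totals may be given as an
#' efficiency \eqn{\varepsilon} (mean UMI per cell), in which case the mean
#' read total is \eqn{\varepsilon M}; the realized total of a simulated
#' sample is stochastic (the sum of per-clone counts) and is never rescaled.
#'
#' @param N Total number of clones in the simulated organism.
#' @param nu Power-law exponent of the clone-size prior.
#' @param noise A [noise_model()].
#' @param n_read,n_read_prime Mean total reads of the two samples.
#' @param efficiency Alternative to `n_read` for the two-step model:
#'   reads per cell \eqn{\varepsilon}, one value or one per sample;
#'   `n_read = efficiency * M`.
#' @param expansion An [expansion_prior()] for expansion simulations
#'   (`NULL` for null/replicate simulations).
#' @param seed Integer RNG seed; identical config + seed gives identical
#'   tables.
#' @param step Frequency-grid spacing used by the quadrant sampler.
#' @return A `simulation_config` object (list).
#' @export
simulation_config <- function(N, nu = 2, noise = noise_model("poisson"),
                              n_read = NULL, n_read_prime = NULL,
                              efficiency = NULL, expansion = NULL,
                              seed = NULL, step = 0.05) {
  stopifnot(inherits(noise, "noise_model"))
  if (is.null(n_read)) {
    if (is.null(efficiency) || noise$kind != "negbin_poisson") {
      rlang::abort("Supply `n_read`, or `efficiency` with a two-step noise model.")
    }
    eff <- rep_len(efficiency, 2)
    n_read <- eff[1] * noise$M
    n_read_prime <- eff[2] * noise$M
  }
  if (is.null(n_read_prime)) n_read_prime <- n_read
  f_min <- solve_fmin(nu, N)
  structure(list(
    N = N, nu = nu, f_min = f_min, noise = noise,
    n_read = n_read, n_read_prime = n_read_prime,
    expansion = expansion, seed = seed, step = step
  ), class = "simulation_config")
}

#' Preset simulation configurations
#'
#' Two standard synthetic regimes: `"mouse"` (\eqn{N = 10^6} clones,
#' \eqn{10^4} reads per sample) and `"human"` (\eqn{N = 10^9} clones,
#' \eqn{10^6} reads per sample), both with \eqn{\nu = 2}, Poisson noise and
#' `f_min` from \eqn{N\langle f\rangle = 1}.
#'
#' @param name `"mouse"` or `"human"`.
#' @param ... Overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
preset_config <- function(name = c("mouse", "human"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    mouse = list(N = 1e6, nu = 2, n_read = 1e4),
    human = list(N = 1e9, nu = 2, n_read = 1e6)
  )
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# stable log(1 - exp(x)) for x < 0
log1mexp <- function(x) {
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}

# exact inverse-cdf draw from the power-law prior (vectorized)
r_powerlaw <- function(k, prior, f_lo = prior$f_min, f_hi = 1) {
  p <- 1 - prior$nu
  u <- stats::runif(k)
  (f_lo^p + u * (f_hi^p - f_lo^p))^(1 / p)
}

#' Zero-truncated count draws
#'
#' Exact draws from the count law restricted to \eqn{n \ge 1},
#' \eqn{P(n \mid f)/P(n > 0 \mid f)}. For Poisson and negative-binomial
#' noise the draw is a stable inverse-cdf in log space (no underflow for
#' tiny \eqn{P(n > 0 \mid f)}). For the two-step law the latent cell count
#' is drawn from its observation-weighted marginal
#' \eqn{P(m \mid f)\,(1 - e^{-m\varepsilon})} (exact categorical for small
#' mean cell counts, rejection for large ones) and the count from a
#' zero-truncated Poisson given \eqn{m}.
#'
#' @param f Vector of frequencies (one draw per element).
#' @param model A [noise_model()].
#' @param n_read Total molecule count of the sample.
#' @return Integer-valued counts \eqn{\ge 1}, same length as `f`.
#' @export
zero_truncated_count <- function(f, model, n_read) {
  stopifnot(inherits(model, "noise_model"))
  k <- length(f)
  if (k == 0) return(integer(0))
  switch(model$kind,
    poisson = zt_pois(f * n_read),
    negbin = {
      if (model$a == 0) return(zt_pois(f * n_read))
      mu <- f * n_read
      size <- nb_size(mu, model$a, model$gamma)
      log_p0 <- -size * log1p(mu / size)
      lu <- log(stats::runif(k)) + log1mexp(log_p0)
      stats::qnbinom(lu, size = size, mu = mu, lower.tail = FALSE, log.p = TRUE)
    },
    negbin_poisson = {
      eps <- n_read / model$M
      m <- zt_nbp_cells(f, model, eps)
      zt_pois(m * eps)
    }
  )
}

# zero-truncated Poisson by inverse cdf in log space
zt_pois <- function(lam) {
  lu <- log(stats::runif(length(lam))) + log1mexp(-lam)
  stats::qpois(lu, lam, lower.tail = FALSE, log.p = TRUE)
}

# latent cell count conditioned on n > 0: P(m|f) (1 - e^(-m eps)) / norm
zt_nbp_cells <- function(f, model, eps) {
  mbar <- f * model$M
  k <- length(f)
  m <- integer(k)
  big <- mbar > 30
  # rejection for large mean cell counts (acceptance ~ 1 - e^(-mbar eps))
  idx <- which(big)
  while (length(idx) > 0) {
    cand <- if (model$a == 0) stats::rpois(length(idx), mbar[idx]) else
      stats::rnbinom(length(idx),
                     size = nb_size(mbar[idx], model$a, model$gamma),
                     mu = mbar[idx])
    acc <- stats::runif(length(idx)) < -expm1(-cand * eps)
    m[idx[acc]] <- cand[acc]
    idx <- idx[!acc]
  }
  # exact categorical over m for small mean cell counts, in chunks
  small <- which(!big)
  if (length(small) > 0) {
    m_top <- max(cell_quantile(1e-12, mbar[small], model, lower.tail = FALSE), 8)
    mm <- seq_len(m_top)  # m = 0 has zero weight under (1 - e^(-m eps))
    wfac <- -expm1(-mm * eps)
    for (start in seq(1, length(small), by = 512L)) {
      ch <- small[start:min(start + 511L, length(small))]
      W <- matrix(cell_pmf(rep(mm, each = length(ch)),
                           rep(mbar[ch], length(mm)), model),
                  length(ch), length(mm))
      W <- sweep(W, 2L, wfac, "*")
      cw <- W %*% upper.tri(diag(length(mm)), diag = TRUE)  # row cumsums
      tot <- cw[, length(mm)]
      u <- stats::runif(length(ch)) * tot
      m[ch] <- mm[max.col(cw >= u, ties.method = "first")]
    }
  }
  m
}

#' Simulate a same-day replicate pair (null model)
#'
#' Draws an observed-clone count table from the null model without ever
#' instantiating the unobserved clones: the number of observed clones is
#' \eqn{N_{\mathrm{obs}} = N(1 - P(0,0))}; each observed clone is assigned
#' to one of the three quadrants of \eqn{(n, n')} space with at least one
#' positive count (\eqn{q_{x0}}, \eqn{q_{0x}}, \eqn{q_{xx}}) according to
#' their analytic weights; its frequency is drawn from the
#' quadrant-conditioned posterior density of \eqn{f} (inverse cdf on the
#' log-frequency grid, exact power-law quantile within a grid cell); and
#' its nonzero counts are drawn from the zero-truncated conditionals.
#' For the two-step noise model the latent cell counts are marginalized in
#' the quadrant weights and conditionals.
#'
#' @param config A [simulation_config()] without expansion prior.
#' @return A [pair_table()] with `N_obs` rows (every row has
#'   \eqn{n + n' > 0}), carrying the realized read totals.
#' @export
sample_null_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$expansion)) {
    rlang::abort("Config has an expansion prior; use sample_expansion_pair().")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  prior <- clone_size_prior(config$nu, f_min = config$f_min)
  g <- frequency_grid(prior, step = config$step)
  cq <- g$cq / sum(g$cq)
  a0 <- noise_zero_prob(config$noise, g$f, config$n_read)
  b0 <- noise_zero_prob(config$noise, g$f, config$n_read_prime)
  P00 <- sum(cq * a0 * b0)
  w_x0 <- cq * (1 - a0) * b0
  w_0x <- cq * a0 * (1 - b0)
  w_xx <- cq * (1 - a0) * (1 - b0)
  norm <- 1 - P00
  q_w <- c(sum(w_x0), sum(w_0x), sum(w_xx)) / norm
  n_obs <- as.integer(round(config$N * norm))
  n_q <- as.integer(stats::rmultinom(1, n_obs, q_w))

  sample_f <- function(k, w) {
    if (k == 0) return(numeric(0))
    cells <- sample.int(length(w), k, replace = TRUE, prob = w)
    # exact truncated power-law quantile within the grid cell around a node
    lo <- exp(pmax(g$lnf[cells] - g$h / 2, log(prior$f_min)))
    hi <- exp(pmin(g$lnf[cells] + g$h / 2, 0))
    r_powerlaw(k, prior, f_lo = lo, f_hi = hi)
  }

  f_x0 <- sample_f(n_q[1], w_x0)
  f_0x <- sample_f(n_q[2], w_0x)
  f_xx <- sample_f(n_q[3], w_xx)

  n <- c(
    zero_truncated_count(f_x0, config$noise, config$n_read),
    rep(0L, n_q[2]),
    zero_truncated_count(f_xx, config$noise, config$n_read)
  )
  n_prime <- c(
    rep(0L, n_q[1]),
    zero_truncated_count(f_0x, config$noise, config$n_read_prime),
    zero_truncated_count(f_xx, config$noise, config$n_read_prime)
  )
  f_all <- c(f_x0, f_0x, f_xx)
  ord <- sample.int(n_obs)  # shuffle quadrant blocks
  out <- tibble::tibble(
    clone_id = sprintf("clone_%07d", seq_len(n_obs)),
    n = as.integer(n[ord]), n_prime = as.integer(n_prime[ord]),
    f = f_all[ord]
  )
  # the table carries the generative read totals: the model constant
  # N_read stays the nominal value, the realized column sum is stochastic
  pair_table(out, n_read = config$n_read, n_read_prime = config$n_read_prime)
}

#' Simulate a two-time-point pair under the expansion model
#'
#' The straightforward full-repertoire scheme: frequencies are drawn from
#' the clone-size prior until they sum to 1 (the last clone takes the sum
#' exactly to 1); each clone receives a log fold-change drawn from the
#' expansion prior (non-responders get \eqn{s = s_0}); second-time-point
#' frequencies are \eqn{f_i' = f_i e^{s_i} / \sum_j f_j e^{s_j}} (so both
#' time points sum exactly to 1); counts are drawn from the noise model at
#' each time point; clones unseen in both samples are discarded, so the
#' number of observed rows is stochastic.
#'
#' @param config A [simulation_config()] whose `expansion` field is an
#'   [expansion_prior()].
#' @return A [pair_table()] with ground-truth columns `f`, `f_prime`, `s`
#'   (realized log fold-change \eqn{\ln(f'/f)}) and `responding` (logical).
#' @export
sample_expansion_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$expansion)) {
    rlang::abort("Config has no expansion prior; use sample_null_pair().")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  prior <- clone_size_prior(config$nu, f_min = config$f_min)

  # draw frequencies until their running sum reaches 1
  fs <- list(); tot <- 0; chunk <- max(1e5, ceiling(config$N / 8))
  repeat {
    x <- r_powerlaw(chunk, prior)
    cs <- tot + cumsum(x)
    hit <- which(cs >= 1)
    if (length(hit) > 0) {
      k <- hit[1]
      last <- 1 - (if (k > 1) cs[k - 1] else tot)
      fs[[length(fs) + 1]] <- c(x[seq_len(k - 1)], last)
      break
    }
    fs[[length(fs) + 1]] <- x
    tot <- cs[chunk]
  }
  f <- unlist(fs)
  k <- length(f)

  ep <- config$expansion
  responding <- stats::runif(k) < ep$alpha
  s <- rep(ep$s0, k)
  nr <- sum(responding)
  if (nr > 0) s[responding] <- ep$s0 + r_expansion_effect(nr, ep)
  fe <- f * exp(s)
  f_prime <- fe / sum(fe)

  n <- sample_counts(f, config$noise, config$n_read)
  n_prime <- sample_counts(f_prime, config$noise, config$n_read_prime)
  keep <- which(n + n_prime > 0L)
  f_k <- f[keep]; fp_k <- f_prime[keep]
  out <- tibble::tibble(
    clone_id = sprintf("clone_%07d", seq_along(keep)),
    n = as.integer(n[keep]), n_prime = as.integer(n_prime[keep]),
    f = f_k, f_prime = fp_k,
    s = log(fp_k / f_k),
    responding = responding[keep]
  )
  pair_table(out, n_read = config$n_read, n_read_prime = config$n_read_prime)
}

# draw the responding-clone effect (the continuous part, relative to s0)
r_expansion_effect <- function(k, ep) {
  switch(ep$family,
    asym_exp = stats::rexp(k, rate = 1 / ep$sbar),
    sym_exp = stats::rexp(k, rate = 1 / ep$sbar) *
      sample(c(-1, 1), k, replace = TRUE),
    gauss_centered = stats::rnorm(k, 0, ep$sbar),
    gauss_offcentered = stats::rnorm(k, ep$s1, ep$sbar)
  )
}
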