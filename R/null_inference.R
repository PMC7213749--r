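# ---- internal likelihood machinery ------------------------------------------

# Discretized joint machinery for a (prior, noise model, read totals) triple:
# grid, rho(f)-weights (renormalized on the grid so the discretized prior is
# proper), and the two pmf matrices over the unique counts of each sample.
null_cache <- function(pairs, prior, model, n_read, n_read_prime,
                       step = 0.05, model2 = model) {
  g <- frequency_grid(prior, step = step)
  cq <- g$cq / sum(g$cq)
  un <- sort(unique(c(0L, pairs$n)))
  unp <- sort(unique(c(0L, pairs$n_prime)))
  A <- count_pmf_matrix(model, g$f, un, n_read)
  B <- count_pmf_matrix(model2, g$f, unp, n_read_prime)
  list(
    g = g, cq = cq, A = A, B = B,
    i_n = match(pairs$n, un), i_np = match(pairs$n_prime, unp),
    w = pairs$weight, n_obs = sum(pairs$weight)
  )
}

# joint probabilities of the observed unique pairs and of (0, 0)
cache_joint <- function(ca) {
  P <- as.numeric(crossprod(ca$cq, ca$A[, ca$i_n, drop = FALSE] *
                              ca$B[, ca$i_np, drop = FALSE]))
  P00 <- sum(ca$cq * ca$A[, 1] * ca$B[, 1])
  list(P = P, P00 = P00)
}

# P(0,0) alone, given prior/model/reads (cheap: only the zero columns)
p00_only <- function(prior, model, n_read, n_read_prime, step = 0.05,
                     model2 = model) {
  g <- frequency_grid(prior, step = step)
  cq <- g$cq / sum(g$cq)
  sum(cq * noise_zero_prob(model, g$f, n_read) *
        noise_zero_prob(model2, g$f, n_read_prime))
}

# The mean constraint N<f> = 1 with the total clone number itself estimated
# at the current parameters, N = N_obs/(1 - P(0,0)), is a scalar equation in
# log10 f_min:  g(x) = log[ N_impl(x) <f>(x) ] = 0.
# At low sequencing depth g can have several roots (branches of the
# constraint surface); the constrained MLE must compare the likelihood
# across branches. fmin_constraint_roots() enumerates all roots on a sweep;
# solve_fmin_fixed_point() returns the root nearest a warm start (branch
# tracking during optimizer refinement) or all roots.

fmin_constraint_g <- function(x, nu, model, n_read, n_read_prime, n_obs,
                              step, model2 = model) {
  prior <- clone_size_prior(nu, f_min = 10^x)
  P00 <- p00_only(prior, model, n_read, n_read_prime, step, model2 = model2)
  if (P00 >= 1 - 1e-12) return(NA_real_)
  log((n_obs / (1 - P00)) * clone_moment(1, prior))
}

fmin_constraint_roots <- function(nu, model, n_read, n_read_prime, n_obs,
                                  step = 0.05, model2 = model,
                                  x_range = c(-15, -0.5), sweep = 0.3,
                                  tol = 1e-7) {
  g <- function(x) fmin_constraint_g(x, nu, model, n_read, n_read_prime,
                                     n_obs, step, model2)
  xs <- seq(x_range[1], x_range[2], by = sweep)
  gs <- vapply(xs, g, numeric(1))
  ok <- which(!is.na(gs[-length(gs)]) & !is.na(gs[-1]) &
                gs[-length(gs)] * gs[-1] <= 0)
  vapply(ok, function(i) {
    stats::uniroot(g, lower = xs[i], upper = xs[i + 1], tol = tol)$root
  }, numeric(1))
}

solve_fmin_fixed_point <- function(nu, model, n_read, n_read_prime, n_obs,
                                   step = 0.05, fm_start = NULL,
                                   tol = 1e-7, model2 = model) {
  roots <- NULL
  if (!is.null(fm_start)) {   # local sweep around the tracked branch
    x0 <- log10(fm_start)
    roots <- fmin_constraint_roots(nu, model, n_read, n_read_prime, n_obs,
                                   step, model2,
                                   x_range = c(x0 - 1.2, min(x0 + 1.2, -0.5)),
                                   sweep = 0.15, tol = tol)
    if (length(roots) > 0) roots <- roots[which.min(abs(roots - x0))]
  }
  if (length(roots) == 0) {
    roots <- fmin_constraint_roots(nu, model, n_read, n_read_prime, n_obs,
                                   step, model2, tol = tol)
  }
  if (length(roots) == 0) {
    rlang::abort("No solution of the normalization constraint N<f> = 1 for these parameters.")
  }
  if (!is.null(fm_start)) roots <- roots[which.min(abs(roots - log10(fm_start)))]
  lapply(roots, function(x) {
    fm <- 10^x
    prior <- clone_size_prior(nu, f_min = fm)
    P00 <- p00_only(prior, model, n_read, n_read_prime, step, model2 = model2)
    list(f_min = fm, N = n_obs / (1 - P00), P00 = P00)
  })
}

# ---- exported operations -----------------------------------------------------

#' Joint likelihood of a replicate count pair
#'
#' \deqn{P(n, n') = \int_{f_{\min}}^{1} df\, \rho(f)\, P(n \mid f)\,
#'   P(n' \mid f),}
#' the probability of observing counts \eqn{(n, n')} for one clone in two
#' replicates sharing the same latent frequency \eqn{f}, computed on the
#' logarithmic frequency grid. Replicates may differ in read totals.
#'
#' @param n,n_prime Vectors of counts (recycled pairwise).
#' @param prior A [clone_size_prior()].
#' @param model A [noise_model()].
#' @param n_read,n_read_prime Read totals of the two samples
#'   (`n_read_prime` defaults to `n_read`).
#' @param step Frequency-grid spacing in \eqn{\ln f}.
#' @return Vector of joint probabilities.
#' @export
pair_likelihood <- function(n, n_prime, prior, model, n_read,
                            n_read_prime = n_read, step = 0.05) {
  pr <- tibble::tibble(n = as.integer(n), n_prime = as.integer(n_prime),
                       weight = 1L)
  ca <- null_cache(pr, prior, model, n_read, n_read_prime, step)
  out <- cache_joint(ca)$P
  if (any(!is.finite(out))) {
    rlang::abort("Non-finite pair likelihood; check parameters (integrand diagnostic).")
  }
  out
}

#' Average conditioned log-likelihood of a pair table
#'
#' The per-clone average of the log-likelihood conditioned on the clone
#' being observed (\eqn{n + n' > 0}):
#' \deqn{\ell = \frac{1}{N_{\mathrm{obs}}}\sum_i \left[\ln P(n_i, n_i')
#'   - \ln\left(1 - P(0,0)\right)\right],}
#' evaluated over unique count pairs with multiplicities.
#'
#' @param tab A [pair_table()].
#' @inheritParams pair_likelihood
#' @return A single number (\eqn{\le 0}).
#' @export
conditioned_log_likelihood <- function(tab, prior, model, step = 0.05) {
  stopifnot(inherits(tab, "pair_table"))
  pairs <- pt_pairs(tab)
  nr <- pt_n_read(tab)
  ca <- null_cache(pairs, prior, model, nr[1], nr[2], step)
  j <- cache_joint(ca)
  if (j$P00 >= 1 - 1e-12) rlang::abort("Degenerate model: P(0,0) ~ 1.")
  if (any(!is.finite(log(j$P)))) {
    rlang::abort("Non-finite log-likelihood: some observed pairs have zero probability under these parameters.")
  }
  sum(pairs$weight * log(j$P)) / ca$n_obs - log1p(-j$P00)
}

#' Realization-specific normalization of the fitted frequencies
#'
#' The normalization statistic
#' \deqn{Z = N\,P(0,0)\,\langle f\rangle_{\rho(f\mid 0,0)} +
#'   \sum_i \langle f\rangle_{\rho(f \mid n_i, n_i')},}
#' the posterior-expected total frequency of the repertoire: the first term
#' is the total frequency of the unseen clones
#' (\eqn{N = N_{\mathrm{obs}}/(1 - P(0,0))}), the second the summed posterior
#' mean frequencies of the observed clones. A well-normalized model has
#' \eqn{Z = 1} for the realized data.
#'
#' @param tab A [pair_table()].
#' @inheritParams pair_likelihood
#' @return `Z` (a single positive number).
#' @export
normalization_Z <- function(tab, prior, model, step = 0.05) {
  stopifnot(inherits(tab, "pair_table"))
  pairs <- pt_pairs(tab)
  nr <- pt_n_read(tab)
  ca <- null_cache(pairs, prior, model, nr[1], nr[2], step)
  j <- cache_joint(ca)
  cf <- ca$cq * ca$g$f
  Pf <- as.numeric(crossprod(cf, ca$A[, ca$i_n, drop = FALSE] *
                               ca$B[, ca$i_np, drop = FALSE]))
  f00 <- sum(cf * ca$A[, 1] * ca$B[, 1]) / j$P00
  N <- ca$n_obs / (1 - j$P00)
  N * j$P00 * f00 + sum(pairs$weight * Pf / j$P)
}

#' Estimated total clone number
#'
#' \eqn{N = N_{\mathrm{obs}} / (1 - P(0,0))}: the observed clone count
#' corrected for the clones missed in both samples.
#'
#' @param tab A [pair_table()].
#' @param fit A `null_fit` from [fit_null()], or `NULL` to supply
#'   `P00` directly.
#' @param P00 Probability that a clone is unseen in both samples.
#' @return Estimated `N` (\eqn{\ge N_{\mathrm{obs}}}).
#' @export
estimate_total_clones <- function(tab, fit = NULL, P00 = fit$P00) {
  stopifnot(inherits(tab, "pair_table"))
  nrow(tab) / (1 - P00)
}

#' Covariance at a constrained optimum from the projected Hessian
#'
#' Error bars for a maximum-likelihood fit subject to one smooth constraint
#' \eqn{C(\theta) = 0}: the Hessian \eqn{H} of the log-likelihood is
#' projected onto the hyperplane tangent to the constraint,
#' \deqn{\hat H = H - PH - HP + PHP, \qquad P = \vec n\,\vec n^\top,}
#' with \eqn{\vec n} the unit normal \eqn{\nabla C/\lVert\nabla C\rVert};
#' the covariance is the Moore-Penrose pseudo-inverse of \eqn{-\hat H},
#' which has exactly one null direction (along the constraint normal).
#'
#' @param hessian Hessian matrix of the log-likelihood at the optimum.
#' @param constraint_gradient Gradient of the constraint at the optimum.
#' @return A list with `covariance` (symmetric PSD matrix, one zero
#'   eigenvalue along the normal), `errors` (per-parameter standard
#'   deviations) and `projected_hessian`.
#' @export
projected_fisher_covariance <- function(hessian, constraint_gradient) {
  nv <- constraint_gradient / sqrt(sum(constraint_gradient^2))
  P <- tcrossprod(nv)
  H <- (hessian + t(hessian)) / 2
  Hp <- H - P %*% H - H %*% P + P %*% H %*% P
  cov <- MASS::ginv(-Hp)
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -0.01 * max(abs(ev)))) {
    warning("Projected Hessian is not negative semi-definite on the constraint subspace; error bars unreliable.")
  }
  # clip finite-difference noise: tiny negative eigenvalues are zeroed
  if (any(ev < 0)) {
    ed <- eigen(cov, symmetric = TRUE)
    cov <- ed$vectors %*% (pmax(ed$values, 0) * t(ed$vectors))
    cov <- (cov + t(cov)) / 2
  }
  list(covariance = cov, errors = sqrt(pmax(diag(cov), 0)),
       projected_hessian = Hp)
}

# assemble theta vector on the optimization scales
theta_vec <- function(kind, nu, a = NA, gamma = NA, M = NA, f_min) {
  switch(kind,
    poisson = c(nu = nu, log10_f_min = log10(f_min)),
    negbin = c(nu = nu, a = a, gamma = gamma, log10_f_min = log10(f_min)),
    negbin_poisson = c(nu = nu, a = a, gamma = gamma, log10_M = log10(M),
                       log10_f_min = log10(f_min))
  )
}

theta_to_models <- function(kind, th) {
  prior <- clone_size_prior(th[["nu"]], f_min = 10^th[["log10_f_min"]])
  model <- switch(kind,
    poisson = noise_model("poisson"),
    negbin = noise_model("negbin", a = th[["a"]], gamma = th[["gamma"]]),
    negbin_poisson = noise_model("negbin_poisson", a = th[["a"]],
                                 gamma = th[["gamma"]], M = 10^th[["log10_M"]])
  )
  list(prior = prior, model = model)
}

#' Fit the null model to a replicate pair
#'
#' Joint maximum-likelihood fit of the clone-size prior and the noise model
#' from a same-day replicate pair, maximizing the average conditioned
#' log-likelihood ([conditioned_log_likelihood()]) subject to a
#' normalization constraint:
#'
#' * `normalization = "mean"` (default): \eqn{N\langle f\rangle = 1}
#'   with \eqn{N = N_{\mathrm{obs}}/(1 - P(0,0))}; `f_min` is eliminated
#'   (solved from the constraint at every objective evaluation) and the
#'   remaining parameters are optimized unconstrained.
#' * `normalization = "realization"`: \eqn{Z = 1}
#'   ([normalization_Z()]); `f_min` is solved from \eqn{Z(\theta)=1} at
#'   every evaluation. Both constraints yield similar estimates; the mean
#'   constraint is cheaper.
#'
#' Optimization is a coarse grid search followed by Nelder-Mead refinement,
#' on the scales \eqn{(\nu, a, \gamma, \log_{10} M, \log_{10} f_{\min})}.
#' Error bars come from the Hessian of the total log-likelihood projected
#' onto the constraint hyperplane ([projected_fisher_covariance()]).
#'
#' @param tab A [pair_table()] of same-day replicates.
#' @param kind Noise-model kind: `"poisson"`, `"negbin"`, `"negbin_poisson"`.
#' @param normalization `"mean"` or `"realization"` (see above).
#' @param step Frequency-grid spacing in \eqn{\ln f}.
#' @param grid Named list of coarse-search values per free parameter
#'   (`nu`, `a`, `gamma`, `log10_M`); sensible defaults cover the ranges
#'   reported for mRNA-based repertoire protocols.
#' @param maxit,reltol Nelder-Mead control.
#' @param hessian Compute the projected-Hessian covariance (default TRUE).
#' @param fd_step Finite-difference step (on each parameter's scale) for
#'   the Hessian and the constraint gradient.
#' @return A `null_fit` object: fitted `theta`, `prior`, `model`, average
#'   conditioned log-likelihood `log_likelihood`, `P00`, estimated total
#'   clone number `N`, realization normalization `Z`, `covariance` and
#'   per-parameter `errors`, plus optimizer diagnostics.
#' @export
fit_null <- function(tab, kind = c("negbin_poisson", "negbin", "poisson"),
                     normalization = c("mean", "realization"),
                     step = 0.05, grid = NULL,
                     maxit = 150, reltol = 1e-7,
                     hessian = TRUE, fd_step = 1e-3) {
  stopifnot(inherits(tab, "pair_table"))
  kind <- match.arg(kind)
  normalization <- match.arg(normalization)
  pairs <- pt_pairs(tab)
  if (nrow(pairs) < 2) {
    rlang::abort("Degenerate table: a single unique count pair gives a flat likelihood.")
  }
  nr <- pt_n_read(tab)
  n_obs <- nrow(tab)

  free <- switch(kind,
    poisson = "nu",
    negbin = c("nu", "a", "gamma"),
    negbin_poisson = c("nu", "a", "gamma", "log10_M")
  )
  default_grid <- list(
    nu = c(1.7, 2.0, 2.4),
    a = c(0.15, 0.45, 0.9),
    gamma = c(1.1, 1.3),
    log10_M = log10(nr[1]) + c(0.25, 0.75)
  )
  grid <- utils::modifyList(default_grid, grid %||% list())

  fm_state <- new.env(parent = emptyenv())
  fm_state$fm <- NULL

  build <- function(x) {
    # x: free parameters; returns prior+model(+ll) with f_min from the
    # constraint. Where the constraint has several branches, the
    # likelihood-preferred one is chosen (warm-started branch tracking once
    # the optimizer is refining).
    nu <- x[["nu"]]
    model <- switch(kind,
      poisson = noise_model("poisson"),
      negbin = noise_model("negbin", a = x[["a"]], gamma = x[["gamma"]]),
      negbin_poisson = noise_model("negbin_poisson", a = x[["a"]],
                                   gamma = x[["gamma"]], M = 10^x[["log10_M"]])
    )
    if (normalization == "mean") {
      cand <- solve_fmin_fixed_point(nu, model, nr[1], nr[2], n_obs, step,
                                     fm_start = if (isTRUE(fm_state$track)) fm_state$fm)
      lls <- vapply(cand, function(fp) {
        tryCatch(
          conditioned_log_likelihood(
            tab, clone_size_prior(nu, f_min = fp$f_min), model, step),
          error = function(e) -Inf
        )
      }, numeric(1))
      if (all(!is.finite(lls))) rlang::abort("Non-finite likelihood on all constraint branches.")
      best <- which.max(lls)
      fm_state$fm <- cand[[best]]$f_min
      list(prior = clone_size_prior(nu, f_min = cand[[best]]$f_min),
           model = model, ll = lls[best])
    } else {
      gfun <- function(lf) {
        pr <- clone_size_prior(nu, f_min = 10^lf)
        normalization_Z(tab, pr, model, step) - 1
      }
      lf0 <- log10(fm_state$fm %||% solve_fmin(nu, n_obs * 10))
      lo <- lf0 - 3; hi <- min(lf0 + 3, -0.05)
      for (tries in 1:4) {
        if (gfun(lo) * gfun(hi) <= 0) break
        lo <- lo - 2; hi <- min(hi + 1, -0.01)
      }
      r <- stats::uniroot(gfun, lower = lo, upper = hi, tol = 1e-9)
      fm_state$fm <- 10^r$root
      list(prior = clone_size_prior(nu, f_min = 10^r$root), model = model)
    }
  }

  objective <- function(x) {
    names(x) <- free
    if (x[["nu"]] <= 1.01) return(-1e10)
    if ("a" %in% free && x[["a"]] < 0) return(-1e10)
    if ("gamma" %in% free && (x[["gamma"]] < 0.5 || x[["gamma"]] > 3)) return(-1e10)
    out <- tryCatch({
      pm <- build(x)
      pm$ll %||% conditioned_log_likelihood(tab, pm$prior, pm$model, step)
    }, error = function(e) -1e10)
    if (!is.finite(out)) -1e10 else out
  }

  # coarse grid search
  gvals <- expand.grid(grid[free], KEEP.OUT.ATTRS = FALSE)
  gll <- apply(as.matrix(gvals), 1, objective)
  if (all(gll <= -1e9)) rlang::abort("No finite likelihood on the coarse grid.")
  fin_ll <- gll[gll > -1e9]
  if (length(fin_ll) >= 2 && diff(range(fin_ll)) < 1e-9) {
    rlang::abort("Flat likelihood over the search grid; the data do not constrain the model.")
  }
  x0 <- as.numeric(gvals[which.max(gll), ])
  names(x0) <- free
  invisible(objective(x0))   # seed the branch tracker at the grid optimum
  fm_state$track <- TRUE

  if (length(free) == 1L) {
    op <- stats::optimize(function(v) objective(c(nu = v)),
                          interval = c(max(1.05, x0 - 0.5), x0 + 0.5),
                          maximum = TRUE, tol = 1e-7)
    x_hat <- c(nu = op$maximum); ll_hat <- op$objective; conv <- 0L
  } else {
    op <- stats::optim(x0, objective, method = "Nelder-Mead",
                       control = list(fnscale = -1, maxit = maxit,
                                      reltol = reltol))
    if (op$convergence != 0) {  # one restart with a fresh simplex
      op2 <- stats::optim(op$par, objective, method = "Nelder-Mead",
                          control = list(fnscale = -1, maxit = maxit,
                                         reltol = reltol))
      if (op2$value >= op$value) op <- op2
    }
    x_hat <- op$par; ll_hat <- op$value; conv <- op$convergence
    if (conv != 0) {
      warning(sprintf(
        "Nelder-Mead did not report convergence (code %d) at [%s]; treat errors with caution.",
        conv, paste(sprintf("%s=%.4g", free, x_hat), collapse = ", ")
      ))
    }
  }

  pm <- build(x_hat)
  P00 <- p00_only(pm$prior, pm$model, nr[1], nr[2], step)
  N <- n_obs / (1 - P00)
  th <- theta_vec(kind,
                  nu = x_hat[["nu"]],
                  a = if ("a" %in% free) x_hat[["a"]] else NA,
                  gamma = if ("gamma" %in% free) x_hat[["gamma"]] else NA,
                  M = if ("log10_M" %in% free) 10^x_hat[["log10_M"]] else NA,
                  f_min = pm$prior$f_min)

  cov <- errors <- NULL
  if (hessian) {
    full_ll <- function(thv) {
      pm2 <- tryCatch(theta_to_models(kind, thv), error = function(e) NULL)
      if (is.null(pm2)) return(NA_real_)
      tryCatch(
        n_obs * conditioned_log_likelihood(tab, pm2$prior, pm2$model, step),
        error = function(e) NA_real_
      )
    }
    constraint <- function(thv) {
      pm2 <- theta_to_models(kind, thv)
      P00i <- p00_only(pm2$prior, pm2$model, nr[1], nr[2], step)
      (n_obs / (1 - P00i)) * clone_moment(1, pm2$prior) - 1
    }
    # The discretized likelihood carries a small quadrature ripple along
    # f_min (grid-cell phase). Differences along the other parameters at
    # fixed f_min are clean (the ripple is a function of f_min alone and
    # cancels), so plain central differences serve everywhere except the
    # f_min diagonal, which is fitted by quadratic regression over several
    # lattice periods to average the ripple out.
    fd <- rep(fd_step, length(th))
    ifm <- which(names(th) == "log10_f_min")
    fd[ifm] <- 2 * step / log(10)
    H <- fd_hessian(full_ll, th, fd)
    xs <- seq(-3, 3, length.out = 11) * step / log(10)
    ys <- vapply(xs, function(d) {
      th2 <- th; th2[ifm] <- th[[ifm]] + d
      full_ll(th2)
    }, numeric(1))
    qfit <- stats::lm(ys ~ xs + I(xs^2))
    H[ifm, ifm] <- 2 * stats::coef(qfit)[[3]]
    gC <- fd_gradient(constraint, th, fd)
    pf <- projected_fisher_covariance(H, gC)
    cov <- pf$covariance
    errors <- pf$errors
    names(errors) <- names(th)
    dimnames(cov) <- list(names(th), names(th))
  }

  structure(list(
    kind = kind, normalization = normalization,
    theta = th, prior = pm$prior, model = pm$model,
    n_read = nr[1], n_read_prime = nr[2],
    log_likelihood = ll_hat, n_obs = n_obs, P00 = P00, N = N,
    Z = normalization_Z(tab, pm$prior, pm$model, step),
    covariance = cov, errors = errors,
    convergence = conv, grid_search = cbind(gvals, log_likelihood = gll),
    step = step
  ), class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat(sprintf("<null_fit>  %s noise, %s normalization\n", x$kind, x$normalization))
  cat("  theta: ", paste(sprintf("%s=%.4g", names(x$theta), x$theta), collapse = ", "), "\n")
  cat(sprintf("  avg conditioned log-lik = %.6f   N_obs = %d   N = %.3g   Z = %.4f\n",
              x$log_likelihood, x$n_obs, x$N, x$Z))
  invisible(x)
}

# central finite-difference Hessian / gradient on the parameter scales;
# h may be a per-parameter step vector
fd_hessian <- function(f, x, h = 1e-3) {
  p <- length(x)
  h <- rep_len(h, p)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < p) for (j in (i + 1):p) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

fd_gradient <- function(f, x, h = 1e-3) {
  p <- length(x)
  h <- rep_len(h, p)
  vapply(seq_len(p), function(i) {
    ei <- replace(numeric(p), i, h[i])
    (f(x + ei) - f(x - ei)) / (2 * h[i])
  }, numeric(1))
}

#' Diversity estimates with uncertainty propagation
#'
#' Hill diversities \eqn{D_\beta} of the fitted repertoire, with
#' uncertainties obtained by Monte Carlo: parameter vectors are drawn from
#' the multivariate Gaussian approximation of the likelihood (the
#' projected-Hessian covariance), draws violating \eqn{\nu > 1} or
#' \eqn{f_{\min} \in (0,1)} are rejected and redrawn, and the standard
#' deviation of \eqn{\log D_\beta} across draws is reported. The total
#' clone number \eqn{N = N_{\mathrm{obs}}/(1 - P(0,0))} is re-derived for
#' every draw.
#'
#' @param fit A `null_fit` with covariance.
#' @param beta Vector of Hill orders (default `c(0, 1, 2)`).
#' @param n_draws Number of Gaussian parameter draws (default 1000).
#' @return A tibble with columns `beta`, `estimate`, `sd_log` (standard
#'   deviation of \eqn{\log D_\beta}), `lower`, `upper` (log-normal 2-sd
#'   interval).
#' @export
diversity_with_errors <- function(fit, beta = c(0, 1, 2), n_draws = 1000) {
  stopifnot(inherits(fit, "null_fit"))
  if (is.null(fit$covariance)) rlang::abort("Fit has no covariance; rerun fit_null(hessian = TRUE).")
  ev <- eigen(fit$covariance, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1e-300))) rlang::abort("Covariance is not positive semi-definite.")
  est <- hill_diversity(beta, fit$prior, N = fit$N)
  if (all(abs(fit$covariance) < 1e-300)) {
    return(tibble::tibble(beta = beta, estimate = est, sd_log = 0,
                          lower = est, upper = est))
  }
  draws <- matrix(NA_real_, 0, length(fit$theta))
  tries <- 0
  while (nrow(draws) < n_draws && tries < 20) {
    cand <- MASS::mvrnorm(n_draws, mu = fit$theta, Sigma = fit$covariance,
                          tol = 1e-6)
    if (is.null(dim(cand))) cand <- matrix(cand, nrow = 1)
    ok <- cand[, "nu"] > 1.001 & cand[, "log10_f_min"] < -1e-6 &
      is.finite(rowSums(cand))
    if ("a" %in% colnames(cand)) ok <- ok & cand[, "a"] >= 0
    draws <- rbind(draws, cand[ok, , drop = FALSE])
    tries <- tries + 1
  }
  draws <- draws[seq_len(min(nrow(draws), n_draws)), , drop = FALSE]
  logD <- matrix(NA_real_, nrow(draws), length(beta))
  for (k in seq_len(nrow(draws))) {
    th <- draws[k, ]
    names(th) <- names(fit$theta)
    pm <- theta_to_models(fit$kind, th)
    P00 <- p00_only(pm$prior, pm$model, fit$n_read, fit$n_read_prime, fit$step)
    Nk <- fit$n_obs / (1 - P00)
    logD[k, ] <- log(hill_diversity(beta, pm$prior, N = Nk))
  }
  sd_log <- apply(logD, 2, stats::sd)
  tibble::tibble(
    beta = beta, estimate = est, sd_log = sd_log,
    lower = est * exp(-2 * sd_log), upper = est * exp(2 * sd_log)
  )
}
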