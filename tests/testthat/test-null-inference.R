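test_that("pair likelihood is a proper, exchangeable distribution over count pairs", {
  pr <- clone_size_prior(2, f_min = 1e-3)
  m <- noise_model("poisson")
  nmax <- 420
  grid <- expand.grid(n = 0:nmax, np = 0:nmax)
  P <- pair_likelihood(grid$n, grid$np, pr, m, 200, 200)
  expect_equal(sum(P), 1, tolerance = 1e-5)
  # exchangeability of replicates with symmetric contexts
  ns <- c(0, 1, 5, 20); nps <- c(3, 7, 0, 2)
  expect_equal(pair_likelihood(ns, nps, pr, m, 150, 150),
               pair_likelihood(nps, ns, pr, m, 150, 150), tolerance = 1e-12)
})

test_that("conditioned average log-likelihood matches a naive per-row loop", {
  tab <- fx_mouse_null_tab()
  small <- pair_table(tibble::as_tibble(tab)[1:200, ],
                      n_read = attr(tab, "n_read"),
                      n_read_prime = attr(tab, "n_read_prime"))
  np <- fx_true_null_mouse()
  ll <- conditioned_log_likelihood(small, np$prior, np$model)
  expect_lt(ll, 0)
  # naive oracle: loop rows, no multiplicity table
  nr <- c(attr(small, "n_read"), attr(small, "n_read_prime"))
  Pi <- vapply(seq_len(nrow(small)), function(i) {
    pair_likelihood(small$n[i], small$n_prime[i], np$prior, np$model,
                    nr[1], nr[2])
  }, numeric(1))
  P00 <- pair_likelihood(0L, 0L, np$prior, np$model, nr[1], nr[2])
  expect_equal(ll, mean(log(Pi)) - log(1 - P00), tolerance = 1e-12)
  # invariance to row order and to duplicating a row's clone
  shuf <- pair_table(tibble::as_tibble(small)[sample.int(200), ],
                     n_read = nr[1], n_read_prime = nr[2])
  expect_equal(conditioned_log_likelihood(shuf, np$prior, np$model), ll,
               tolerance = 1e-12)
})

test_that("Poisson-kind fit on Poisson data recovers the exponent", {
  fit <- fx_mouse_null_fit()
  expect_lt(abs(fit$theta[["nu"]] - 2), 0.05)
  expect_equal(fit$Z, 1, tolerance = 0.05)
  expect_gt(fit$N, nrow(fx_mouse_null_tab()))
  # errors exist and the recovery is within 3 projected-Hessian sd
  expect_lt(abs(fit$theta[["nu"]] - 2) / fit$errors[["nu"]], 3)
  # tidy/glance accessors
  td <- tidy(fit)
  expect_identical(td$term, names(fit$theta))
  expect_identical(nrow(glance(fit)), 1L)
})

test_that("degenerate tables fail gracefully", {
  flat <- pair_table(data.frame(clone_id = sprintf("c%d", 1:50),
                                n = rep(1000L, 50), n_prime = rep(1000L, 50)))
  expect_error(fit_null(flat, "poisson"), "unique count pair")
})

test_that("total-clone estimate follows the unseen-clone correction", {
  tab <- fx_mouse_null_tab()
  expect_equal(estimate_total_clones(tab, P00 = 0.9), nrow(tab) * 10)
  expect_equal(estimate_total_clones(tab, P00 = 0), nrow(tab))
  fit <- fx_mouse_null_fit()
  # simulated mouse config: N recovered within a factor 1.5
  expect_lt(abs(log(fit$N / 1e6)), log(1.5))
})

test_that("realization normalization Z is ~1 at the fit and monotone in f_min nearby", {
  tab <- fx_mouse_null_tab()
  fit <- fx_mouse_null_fit()
  expect_equal(normalization_Z(tab, fit$prior, fit$model), fit$Z)
  expect_lt(abs(fit$Z - 1), 0.05)
  fm <- fit$prior$f_min
  Zs <- vapply(fm * c(0.5, 1, 2), function(f) {
    normalization_Z(tab, clone_size_prior(fit$theta[["nu"]], f_min = f), fit$model)
  }, numeric(1))
  expect_true(all(diff(Zs) > 0) || all(diff(Zs) < 0))
})

test_that("projected-Hessian covariance matches the bordered-Hessian solution on a quadratic", {
  set.seed(105)
  A <- crossprod(matrix(rnorm(25), 5)) + diag(5) * 0.5
  cvec <- rnorm(5)
  pf <- projected_fisher_covariance(-A, cvec)
  S <- solve(A)
  Vb <- S - S %*% cvec %*% solve(t(cvec) %*% S %*% cvec) %*% t(cvec) %*% S
  expect_equal(pf$covariance, Vb, tolerance = 1e-10)
  # exactly one null direction, along the constraint normal
  ev <- eigen(pf$covariance, symmetric = TRUE)
  expect_equal(sum(ev$values < 1e-10 * max(ev$values)), 1L)
  nv <- cvec / sqrt(sum(cvec^2))
  expect_equal(abs(sum(ev$vectors[, 5] * nv)), 1, tolerance = 1e-8)
  # projection is idempotent
  P <- tcrossprod(nv)
  Hp <- pf$projected_hessian
  expect_equal(Hp - P %*% Hp - Hp %*% P + P %*% Hp %*% P, Hp, tolerance = 1e-12)
  # diagonal Hessian with the constraint along one axis leaves the others alone
  D <- diag(c(4, 9, 16))
  pf2 <- projected_fisher_covariance(-D, c(1, 0, 0))
  expect_equal(diag(pf2$covariance), c(0, 1 / 9, 1 / 16), tolerance = 1e-12)
})

test_that("diversity uncertainties propagate the parameter covariance", {
  fit <- fx_mouse_null_fit()
  set.seed(106)
  div <- diversity_with_errors(fit, n_draws = 400)
  expect_identical(div$beta, c(0, 1, 2))
  expect_equal(div$estimate[1], fit$N)
  expect_true(all(div$sd_log > 0))
  expect_true(all(div$lower < div$estimate & div$estimate < div$upper))
  # error of the error: two independent Monte-Carlo runs agree within ~10%
  set.seed(107)
  div2 <- diversity_with_errors(fit, n_draws = 400)
  expect_equal(div$sd_log, div2$sd_log, tolerance = 0.25)
  # zero covariance -> zero error bars
  fit0 <- fit
  fit0$covariance <- fit$covariance * 0
  expect_equal(diversity_with_errors(fit0)$sd_log, rep(0, 3))
})
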