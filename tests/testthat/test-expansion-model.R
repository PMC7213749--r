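test_that("expansion prior densities match their analytic forms and mixture structure", {
  s <- seq(-14, 14, by = 0.01)
  ep <- expansion_prior("sym_exp", alpha = 0.3, sbar = 0.8, s0 = -0.2)
  d <- expansion_density(s, ep)
  expect_equal(d$atom_weight, 0.7)
  expect_equal(d$continuous, 0.3 * exp(-abs(s + 0.2) / 0.8) / 1.6,
               tolerance = 1e-12)
  # continuous part integrates to alpha
  expect_equal(sum(d$continuous) * 0.01, 0.3, tolerance = 1e-4)
  # one-sided exponential has no mass below s0
  ea <- expansion_prior("asym_exp", alpha = 0.5, sbar = 1, s0 = -0.2)
  da <- expansion_density(s, ea)
  expect_true(all(da$continuous[s < -0.2] == 0))
  # Riemann sum across the support-edge jump is only first-order accurate
  expect_equal(sum(da$continuous) * 0.01, 0.5, tolerance = 0.01)
  # alpha = 0 puts everything in the atom
  e0 <- expansion_prior("sym_exp", alpha = 0, sbar = 1)
  expect_equal(expansion_density(s, e0)$atom_weight, 1)
  expect_error(expansion_prior("sym_exp", alpha = 1.2, sbar = 1), "alpha")
  expect_error(expansion_prior("sym_exp", alpha = 0.1, sbar = -1), "sbar")
})

test_that("the expansion likelihood reduces to the replicate likelihood when the prior collapses", {
  np <- fx_true_null_mouse()
  ep <- expansion_prior("sym_exp", alpha = 0, sbar = 1, s0 = 0)
  ns <- c(0L, 1L, 4L, 30L); nps <- c(2L, 1L, 0L, 28L)
  got <- pair_likelihood_expansion(ns, nps, np, ep, 1e4, 1e4)
  ref <- pair_likelihood(ns, nps, np$prior, np$model, 1e4, 1e4)
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("the expansion likelihood matches an independent adaptive quadrature oracle", {
  pr <- clone_size_prior(2, N = 1e5)
  np <- list(prior = pr, model = noise_model("poisson"))
  ep <- expansion_prior("sym_exp", alpha = 0.2, sbar = 1, s0 = -0.2)
  R <- 5e4
  oracle <- function(n, nprime) {
    fint <- function(s) vapply(s, function(si) {
      stats::integrate(function(lf) {
        f <- exp(lf)
        clone_density(f, pr) * f * dpois(n, f * R) * dpois(nprime, f * exp(si) * R)
      }, log(pr$f_min), 0, rel.tol = 1e-11)$value
    }, numeric(1))
    cont <- stats::integrate(function(s) 0.2 * exp(-abs(s + 0.2) / 1) / 2 * fint(s),
                             -16, 16, rel.tol = 1e-10)$value
    cont + 0.8 * fint(-0.2)
  }
  got <- pair_likelihood_expansion(c(3L, 10L, 0L), c(7L, 2L, 5L), np, ep,
                                   R, R, step = 0.002, s_max = 16)
  expect_equal(got, c(oracle(3, 7), oracle(10, 2), oracle(0, 5)),
               tolerance = 1e-6)
})

test_that("the contraction shift solves the equal-size constraint", {
  tab <- fx_exp_tab()
  np <- fx_true_null_mouse()
  ca <- clonexpand:::expansion_cache(tab, np)
  # alpha = 0: both time points identical on average, no shift
  expect_equal(solve_s0(0, 1, cache = ca), 0, tolerance = 1e-12)
  # closed form: s0 = -log(Z'_0/Z_0)
  ep0 <- expansion_prior("sym_exp", alpha = 0.05, sbar = 1, s0 = 0)
  w0 <- clonexpand:::mix_weights(ca, ep0)
  z <- clonexpand:::cache_exp_Z(ca, w0, ep0)
  expect_equal(solve_s0(0.05, 1, cache = ca), -log(z[["Zp"]] / z[["Z"]]),
               tolerance = 1e-12)
  # more expansion mass drives a stronger global contraction
  s0s <- vapply(c(0.005, 0.02, 0.08), function(a) solve_s0(a, 1, cache = ca),
                numeric(1))
  expect_true(all(diff(s0s) < 0))
  expect_true(all(s0s < 0))
})

test_that("the expansion fit recovers the generating parameters in the regular regime", {
  fit <- fx_exp_fit()
  # generated at (alpha, sbar) = (0.01, 1); ridge scatter allows a factor ~2
  expect_lt(abs(log(fit$sbar / 1)), log(2.5))
  expect_lt(abs(log(fit$alpha * fit$sbar / 0.01)), log(3))
  expect_lt(fit$s0, 0)
  # the likelihood surface shows the diagonal ridge: the covariance major
  # axis has opposite-signed loadings on (log alpha, log sbar)
  ev <- eigen(fit$covariance, symmetric = TRUE)$vectors[, 1]
  expect_lt(prod(sign(ev)), 0)
  td <- tidy(fit)
  expect_true(all(c("alpha", "sbar", "s0") %in% td$term))
})

test_that("EM updates ascend the likelihood and land on the gradient MLE of sbar", {
  ep <- expansion_prior("sym_exp", alpha = 1, sbar = 0.5)
  cfg <- simulation_config(N = 1e6, nu = 2, n_read = 1e5, expansion = ep,
                           seed = 83)
  tab <- sample_expansion_pair(cfg)
  np <- fx_true_null_mouse()
  ca <- NULL; sb <- 1.5; lls <- numeric(0)
  for (it in 1:60) {
    up <- em_update_sbar(tab, np, sb, cache = ca)
    ca <- up$cache
    lls <- c(lls, up$log_likelihood)
    if (abs(up$sbar - sb) < 1e-8) { sb <- up$sbar; break }
    sb <- up$sbar
  }
  expect_true(all(diff(lls) > -1e-10))  # monotone ascent
  gr <- seq(sb - 0.03, sb + 0.03, length.out = 121)
  llg <- vapply(gr, function(s) em_update_sbar(tab, np, s, cache = ca)$log_likelihood,
                numeric(1))
  expect_lt(abs(gr[which.max(llg)] - sb), 1e-3)
})

test_that("the generating prior family wins (or ties) the family comparison", {
  ep <- expansion_prior("sym_exp", alpha = 0.05, sbar = 1)
  cfg <- preset_config("mouse", expansion = ep, seed = 82)
  tab <- sample_expansion_pair(cfg)
  cmp <- compare_prior_families(tab, fx_true_null_mouse())
  expect_setequal(cmp$family, c("asym_exp", "sym_exp", "gauss_centered",
                                "gauss_offcentered"))
  best <- max(cmp$log_likelihood)
  expect_lt(best - cmp$log_likelihood[cmp$family == "sym_exp"], 1e-3)
  # strictly off-centered Gaussian respects its constraint
  expect_gte(cmp$s1[cmp$family == "gauss_offcentered"], 0.1)
})

test_that("a larger, deeper repertoire constrains the expansion parameters more tightly", {
  fit_mouse <- fixture("exp_fit_shallow", function() {
    ep <- expansion_prior("asym_exp", alpha = 0.01, sbar = 1)
    tab <- sample_expansion_pair(preset_config("mouse", expansion = ep, seed = 91))
    fit_expansion(tab, fx_true_null_mouse(), family = "asym_exp")
  })
  fit_deep <- fx_exp_fit()
  # inverse-Fisher ellipse area shrinks with sample size/depth
  expect_lt(det(fit_deep$covariance), det(fit_mouse$covariance))
})
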