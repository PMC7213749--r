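test_that("posterior grids are proper distributions with an exact atom", {
  np <- fx_true_null_mouse()
  ep <- expansion_prior("sym_exp", alpha = 0.05, sbar = 1, s0 = -0.02)
  po <- posterior_s(10, 25, np, ep, 1e4)
  expect_equal(sum(po$density * po$h) + po$atom_weight, 1, tolerance = 1e-6)
  expect_true(all(diff(po$cdf) >= -1e-12))
  expect_gte(min(po$cdf), 0)
  expect_equal(max(po$cdf), 1, tolerance = 1e-6)
  # alpha = 0: all posterior mass on the atom, p_null certain when s0 < 0
  po0 <- posterior_s(10, 25, np, expansion_prior("sym_exp", 0, 1, s0 = -0.1), 1e4)
  expect_equal(po0$atom_weight, 1)
  expect_equal(p_null(po0), 1)
  expect_equal(posterior_summaries(po0)$s_mean, -0.1)
  expect_equal(posterior_summaries(po0)$s_median, -0.1)
})

test_that("p_null tail conventions are exact and self-consistent", {
  # hand-built symmetric posterior about 0 with no atom
  h <- 0.1
  s <- seq(-5, 5, by = h)
  dens <- dnorm(s); dens <- dens / (sum(dens) * h)
  po <- structure(list(s = s, density = dens, atom_weight = 0, atom_s = 0,
                       cdf = cumsum(dens * h), f_mean = 1e-4, h = h),
                  class = "posterior_grid")
  expect_equal(p_null(po), 0.5, tolerance = 1e-12)
  # sum rule on a real posterior: P(s <= 0) + P(s > 0) = 1
  np <- fx_true_null_mouse()
  ep <- expansion_prior("sym_exp", alpha = 0.05, sbar = 1, s0 = -0.02)
  ca <- clonexpand:::expansion_cache(
    pair_table(data.frame(clone_id = "x", n = 4L, n_prime = 9L),
               n_read = 1e4, n_read_prime = 1e4), np)
  pc <- clonexpand:::cache_posteriors(ca, ep)
  expect_equal(clonexpand:::post_p_le(pc, 0) + clonexpand:::post_p_ge(pc, 0),
               1, tolerance = 1e-10)
})

test_that("posterior width narrows as both counts grow", {
  np <- fx_true_null_mouse()
  ep <- expansion_prior("sym_exp", alpha = 0.05, sbar = 1, s0 = -0.01)
  wid <- vapply(list(c(10, 10), c(1000, 1000)), function(p) {
    po <- posterior_s(p[1], p[2], np, ep, 1e6)
    m <- po$density * po$h
    mu <- sum(po$s * m) + po$atom_weight * po$atom_s
    sqrt(sum((po$s - mu)^2 * m) + po$atom_weight * (po$atom_s - mu)^2)
  }, numeric(1))
  expect_lt(wid[2], wid[1] / 5)
})

test_that("p_null is stable under grid refinement", {
  np <- fx_true_null_mouse()
  ep <- expansion_prior("sym_exp", alpha = 0.05, sbar = 1, s0 = -0.02)
  p1 <- p_null(posterior_s(3, 12, np, ep, 1e4, step = 0.05))
  p2 <- p_null(posterior_s(3, 12, np, ep, 1e4, step = 0.025))
  expect_lt(abs(p1 - p2), 1e-3)
})

test_that("the posterior mode of a (0, n') pair jumps to large s as sbar grows", {
  np <- fx_true_null_mouse()
  modes <- vapply(c(0.3, 3), function(ss) {
    epx <- expansion_prior("asym_exp", alpha = 0.01 / ss, sbar = ss, s0 = -0.02)
    po <- posterior_s(0, 9, np, epx, 1e4)
    po$s[which.max(po$density)]
  }, numeric(1))
  expect_lt(modes[1], 2)
  expect_gt(modes[2], 5)
})

test_that("naive log fold-change is antisymmetric and undefined at zero counts", {
  expect_equal(naive_log_fold_change(10, 10), 0)
  expect_equal(naive_log_fold_change(1, 8), log(8))
  n <- c(3, 7, 2); np <- c(9, 1, 5)
  expect_equal(naive_log_fold_change(n, np), -naive_log_fold_change(np, n))
  expect_true(is.na(naive_log_fold_change(0, 5)))
  expect_true(is.na(naive_log_fold_change(5, 0)))
})

test_that("detection calls obey the threshold, monotone staircase, and tie rule", {
  tab <- fx_exp_tab()
  fit <- fx_exp_fit()
  calls <- detect_responding(tab, exp_prior = fit)
  expect_identical(nrow(calls), nrow(tab))
  expect_true(all(calls$p_null_expand >= 0 & calls$p_null_expand <= 1))
  expect_identical(calls$call[calls$p_null_expand < 0.025],
                   rep("expanded", sum(calls$p_null_expand < 0.025)))
  # monotone staircase: p_null_expand decreases in n' at fixed n
  np <- fx_true_null_mouse()
  pn <- vapply(c(5, 10, 20, 40, 80), function(k) {
    p <- posterior_s(3, k, np, fit$prior, attr(tab, "n_read"),
                     attr(tab, "n_read_prime"))
    clonexpand:::post_p_le(
      list(cont = matrix(p$density * p$h, 1), atom = p$atom_weight,
           s = p$s, atom_s = p$atom_s), 0, include_atom = TRUE)
  }, numeric(1))
  expect_true(all(diff(pn) < 0))
  # true responders are enriched among expansion calls
  prec <- mean(tab$responding[calls$call == "expanded"])
  expect_gt(prec, 10 * mean(tab$responding))
})

test_that("a null experiment yields (almost) no calls at the default threshold", {
  tab <- fx_mouse_null_tab()
  nf <- fx_mouse_null_fit()
  ef <- fit_expansion(tab, nf, family = "sym_exp", hessian = FALSE)
  calls <- detect_responding(tab, exp_prior = ef)
  expect_lt(mean(calls$call == "expanded"), 0.025)
  expect_lt(mean(calls$call == "contracted"), 0.025)
})

test_that("the Bayesian median is more conservative than the naive estimator for small clones", {
  tab <- fx_exp_tab()
  fit <- fx_exp_fit()
  calls <- detect_responding(tab, exp_prior = fit)
  both <- !is.na(calls$s_naive)
  small <- both & calls$n + calls$n_prime <= 10 & calls$s_naive != 0
  expect_gt(mean(abs(calls$s_median[small]) <= abs(calls$s_naive[small])), 0.95)
  # agreement for large clones
  big <- both & calls$n >= 200 & calls$n_prime >= 200
  expect_lt(median(abs(calls$s_median[big] - calls$s_naive[big])), 0.1)
})

test_that("list overlap is the Jaccard index with the empty-list convention", {
  expect_equal(list_overlap(c("a", "b"), c("a", "b")), 1)
  expect_equal(list_overlap(c("a"), c("b")), 0)
  expect_equal(list_overlap(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(list_overlap(character(0), character(0)), 0)
})
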