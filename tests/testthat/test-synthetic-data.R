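test_that("configs derive f_min from the mean constraint and seeds give identical tables", {
  cfg <- preset_config("mouse", seed = 42)
  expect_equal(1e6 * clone_moment(1, clone_size_prior(2, f_min = cfg$f_min)),
               1, tolerance = 1e-9)
  t1 <- sample_null_pair(cfg)
  t2 <- sample_null_pair(preset_config("mouse", seed = 42))
  expect_identical(t1$n, t2$n)
  expect_identical(t1$n_prime, t2$n_prime)
  t3 <- sample_null_pair(preset_config("mouse", seed = 43))
  expect_false(identical(t1$n, t3$n))
})

test_that("quadrant weights are analytic, normalized, and exchangeable", {
  cfg <- preset_config("mouse", seed = 44)
  pr <- clone_size_prior(cfg$nu, f_min = cfg$f_min)
  g <- frequency_grid(pr)
  cq <- g$cq / sum(g$cq)
  a0 <- noise_zero_prob(cfg$noise, g$f, cfg$n_read)
  b0 <- noise_zero_prob(cfg$noise, g$f, cfg$n_read_prime)
  P00 <- sum(cq * a0 * b0)
  w <- c(sum(cq * (1 - a0) * b0), sum(cq * a0 * (1 - b0)),
         sum(cq * (1 - a0) * (1 - b0))) / (1 - P00)
  expect_equal(sum(w), 1, tolerance = 1e-10)
  expect_equal(w[1], w[2], tolerance = 1e-12)  # symmetric efficiencies
  # empirical quadrant occupancies agree within 3 sigma binomial error
  tab <- sample_null_pair(cfg)
  k <- nrow(tab)
  emp <- c(mean(tab$n > 0 & tab$n_prime == 0), mean(tab$n == 0 & tab$n_prime > 0))
  for (i in 1:2) {
    expect_lt(abs(emp[i] - w[i]), 3 * sqrt(w[i] * (1 - w[i]) / k))
  }
})

test_that("zero-truncated draws are exact for all three noise kinds", {
  set.seed(108)
  R <- 5e4
  mods <- list(noise_model("poisson"),
               noise_model("negbin", a = 0.7, gamma = 1.3),
               fx_nbp_noise())
  for (mod in mods) {
    x <- zero_truncated_count(rep(2e-5, 4e4), mod, R)
    expect_true(all(x >= 1))
    nmax <- max(x) + 20
    p <- count_pmf(0:nmax, 2e-5, mod, R)
    pc <- p[-1] / (1 - p[1])
    expect_lt(abs(mean(x) - sum((1:nmax) * pc)),
              3 * sqrt(sum((1:nmax)^2 * pc) / 4e4))
    ob <- tabulate(x, nbins = nmax); ex <- 4e4 * pc
    keep <- ex > 5
    chi <- sum((ob[keep] - ex[keep])^2 / ex[keep])
    expect_gt(pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.01)
  }
  # truncated-Poisson mean closed form
  lam <- 0.3
  y <- zero_truncated_count(rep(lam / 100, 5e4), noise_model("poisson"), 100)
  expect_lt(abs(mean(y) - lam / (1 - exp(-lam))), 3 * sqrt(0.3 / 5e4) * 2)
  # far from truncation the draw is indistinguishable from the plain law
  set.seed(109)
  z <- zero_truncated_count(rep(2e-3, 2e4), noise_model("poisson"), 5e4)
  z0 <- rpois(2e4, 100)
  expect_gt(suppressWarnings(ks.test(z, z0)$p.value), 0.01)
})

test_that("the quadrant-conditioned sampler agrees with naive full-repertoire rejection", {
  set.seed(110)
  N <- 1e4
  cfg <- simulation_config(N = N, nu = 2, n_read = 2000, seed = 45)
  pr <- clone_size_prior(2, f_min = cfg$f_min)
  reps <- 12
  tabs <- lapply(seq_len(reps), function(i) {
    sample_null_pair(simulation_config(N = N, nu = 2, n_read = 2000, seed = 450 + i))
  })
  qn <- unlist(lapply(tabs, `[[`, "n"))
  qnp <- unlist(lapply(tabs, `[[`, "n_prime"))
  # naive: instantiate every clone, sample counts, discard double zeros
  nn <- nnp <- integer(0)
  for (i in seq_len(reps)) {
    f <- clonexpand:::r_powerlaw(N, pr)
    a <- sample_counts(f, cfg$noise, cfg$n_read)
    b <- sample_counts(f, cfg$noise, cfg$n_read_prime)
    keep <- a + b > 0
    nn <- c(nn, a[keep]); nnp <- c(nnp, b[keep])
  }
  # two-sample chi-square on the binned joint distribution
  brk <- c(-0.5, 0.5, 1.5, 2.5, 4.5, 8.5, 16.5, Inf)
  f1 <- table(cut(qn, brk), cut(qnp, brk))
  f2 <- table(cut(nn, brk), cut(nnp, brk))
  keep <- (f1 + f2) >= 10
  p1 <- f1[keep] / sum(f1); p2 <- f2[keep] / sum(f2)
  chi <- sum((f1[keep] - sum(f1) * (f1[keep] + f2[keep]) / (sum(f1) + sum(f2)))^2 /
               (sum(f1) * (f1[keep] + f2[keep]) / (sum(f1) + sum(f2)))) +
         sum((f2[keep] - sum(f2) * (f1[keep] + f2[keep]) / (sum(f1) + sum(f2)))^2 /
               (sum(f2) * (f1[keep] + f2[keep]) / (sum(f1) + sum(f2))))
  expect_gt(pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("expansion sampling normalizes both time points exactly and labels ground truth", {
  ep <- expansion_prior("asym_exp", alpha = 0.01, sbar = 1)
  cfg <- simulation_config(N = 1e5, nu = 2, n_read = 3e3, expansion = ep, seed = 46)
  tab <- sample_expansion_pair(cfg)
  expect_true(all(c("f", "f_prime", "s", "responding") %in% names(tab)))
  expect_true(all(tab$n + tab$n_prime > 0))
  # frequencies of the full repertoire summed exactly to 1 before discarding;
  # the retained fractions must not exceed 1
  expect_lte(sum(tab$f), 1)
  expect_lte(sum(tab$f_prime), 1)
  expect_equal(tab$s, log(tab$f_prime / tab$f), tolerance = 1e-12)
  # non-responders all share the global shift realized by renormalization
  s_nr <- tab$s[!tab$responding]
  expect_lt(diff(range(s_nr)), 1e-9)
  expect_lt(s_nr[1], 0)  # expansion of a few is compensated by slight contraction
})

test_that("an alpha = 0 expansion simulation is distributed like a null simulation", {
  set.seed(111)
  ep <- expansion_prior("sym_exp", alpha = 0, sbar = 1)
  cfg <- simulation_config(N = 1e5, nu = 2, n_read = 5e3, expansion = ep, seed = 47)
  te <- sample_expansion_pair(cfg)
  tn <- sample_null_pair(simulation_config(N = 1e5, nu = 2, n_read = 5e3, seed = 48))
  brk <- c(-0.5, 0.5, 1.5, 2.5, 4.5, 8.5, 16.5, Inf)
  f1 <- table(cut(c(te$n, te$n_prime), brk))
  f2 <- table(cut(c(tn$n, tn$n_prime), brk))
  chi <- suppressWarnings(chisq.test(rbind(as.numeric(f1), as.numeric(f2))))
  expect_gt(chi$p.value, 0.01)
})

test_that("simulated marginal counts match the analytic marginal distribution", {
  tabs <- lapply(1:10, function(i) sample_null_pair(preset_config("mouse", seed = 500 + i)))
  n <- unlist(lapply(tabs, `[[`, "n"))
  n <- n[n > 0]
  pr <- clone_size_prior(2, N = 1e6)
  ns <- 1:max(n)
  pm <- marginal_count_pmf(c(0L, ns), pr, noise_model("poisson"), 1e4)
  pc <- pm$prob[-1] / (1 - pm$prob[1])
  ob <- tabulate(n, nbins = max(n)); ex <- length(n) * pc
  keep <- ex >= 5
  chi <- sum((ob[keep] - ex[keep])^2 / ex[keep])
  expect_gt(pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.01)
})
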