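# posterior over s for the unique pairs of a cache, under a fitted prior.
# Returns continuous node masses (lattice), the atom weight per pair, and
# posterior mean initial frequency.
cache_posteriors <- function(ca, ep) {
  wts <- mix_weights(ca, ep)
  K <- nrow(ca$Tm) - 1L
  Tm <- ca$Tm[seq_len(K), , drop = FALSE]
  T1 <- ca$T1[seq_len(K), , drop = FALSE]
  cont <- sweep(Tm, 2L, wts$cont, "*")          # K x nshift node masses
  atom <- wts$atom_w * wts$atom$Tm[seq_len(K)]
  tot <- rowSums(cont) + atom
  if (any(tot <= 0)) {
    rlang::abort("Zero posterior mass for some count pair; the prior cannot explain the data (diagnostic: check s_max and the null parameters).")
  }
  f_num <- as.numeric(T1 %*% wts$cont) + wts$atom_w * wts$atom$T1[seq_len(K)]
  list(cont = cont / tot, atom = atom / tot, f_mean = f_num / tot,
       s = ca$s, atom_s = ep$s0)
}

# tail probabilities with the lattice-cell convention: the mass at node
# s_j represents the cell (s_j - h/2, s_j + h/2], so the node straddling a
# boundary contributes half to each side; the atom sits exactly at s0.
# The non-responding atom counts as evidence against response in *both*
# directions (include_atom = TRUE): s0 is the global renormalization shift,
# so a clone on the atom is a non-responder even though s0 < 0 formally
# means a slight contraction.
post_p_le <- function(po, x = 0, include_atom = FALSE) {
  below <- po$s < x - 1e-12
  at <- abs(po$s - x) < 1e-12
  as.numeric(po$cont %*% (below + 0.5 * at)) +
    po$atom * (include_atom | po$atom_s <= x + 1e-12)
}

post_p_ge <- function(po, x = 0, include_atom = FALSE) {
  above <- po$s > x + 1e-12
  at <- abs(po$s - x) < 1e-12
  as.numeric(po$cont %*% (above + 0.5 * at)) +
    po$atom * (include_atom | po$atom_s >= x - 1e-12)
}

#' Posterior over the log fold-change of one clone
#'
#' Bayes' rule for the expansion factor given the observed count pair:
#' \deqn{\rho(s \mid n, n') \propto \rho_s(s) \int P(n \mid f)\,
#'   P(n' \mid f e^s)\, \rho(f)\, df.}
#' The \eqn{\delta(s - s_0)} atom of the prior (the non-responding
#' component) is carried analytically — it appears as an explicit jump in
#' the cdf, never binned — and the continuous part is evaluated on the
#' shift lattice.
#'
#' @param n,n_prime Observed counts at the two time points (single pair).
#' @param null A `null_fit` or `list(prior=, model=)`.
#' @param exp_prior A fitted [expansion_prior()] (with its solved `s0`).
#' @param n_read,n_read_prime Read totals of the two samples.
#' @inheritParams pair_likelihood_expansion
#' @return A `posterior_grid`: list with `s` (lattice nodes), `density`
#'   (continuous posterior density), `atom_weight`, `atom_s`, `cdf`
#'   (including the atom jump), and `f_mean` (posterior mean initial
#'   frequency).
#' @export
posterior_s <- function(n, n_prime, null, exp_prior,
                        n_read, n_read_prime = n_read,
                        s_max = 12, step = 0.05) {
  stopifnot(length(n) == 1L, length(n_prime) == 1L)
  tab <- pair_table(
    tibble::tibble(clone_id = "x", n = n, n_prime = n_prime),
    n_read = n_read, n_read_prime = n_read_prime
  )
  ca <- expansion_cache(tab, null, s_max = s_max, step = step)
  po <- cache_posteriors(ca, exp_prior)
  new_posterior_grid(po, 1L, ca$h)
}

new_posterior_grid <- function(po, k, h) {
  mass <- po$cont[k, ]
  cdf <- cumsum(mass) + po$atom[k] * (po$atom_s <= po$s + 1e-12)
  structure(list(
    s = po$s, density = mass / h, atom_weight = po$atom[k],
    atom_s = po$atom_s, cdf = cdf, f_mean = po$f_mean[k], h = h
  ), class = "posterior_grid")
}

#' @export
print.posterior_grid <- function(x, ...) {
  cat(sprintf(
    "<posterior_grid>  %d nodes, atom %.4g at s0 = %.4g; P(s <= 0) = %.4g\n",
    length(x$s), x$atom_weight, x$atom_s, p_null(x)
  ))
  invisible(x)
}

#' Posterior probability of not expanding
#'
#' \eqn{P_{\mathrm{null}} = P(s \le 0 \mid n, n')}: the Bayesian
#' counterpart of a p-value — the probability, given the observations, that
#' the clone did not expand. Includes the non-responding atom whenever
#' \eqn{s_0 \le 0}. Clones with \eqn{P_{\mathrm{null}}} below a threshold
#' (0.025 by convention) are called expanded.
#'
#' @param posterior A `posterior_grid` from [posterior_s()].
#' @return A probability in \eqn{[0, 1]}.
#' @export
p_null <- function(posterior) {
  stopifnot(inherits(posterior, "posterior_grid"))
  po <- list(cont = matrix(posterior$density * posterior$h, 1),
             atom = posterior$atom_weight, s = posterior$s,
             atom_s = posterior$atom_s)
  min(1, post_p_le(po, 0))
}

#' Posterior summaries of the log fold-change
#'
#' The posterior mean \eqn{\langle s\rangle = \int s\,\rho(s\mid n,n')ds}
#' (atom included), the posterior median (inverse cdf with atom-aware
#' plateau handling), and the posterior mean initial frequency.
#'
#' @param posterior A `posterior_grid`.
#' @return A tibble with columns `s_mean`, `s_median`, `f_mean`.
#' @export
posterior_summaries <- function(posterior) {
  stopifnot(inherits(posterior, "posterior_grid"))
  mass <- posterior$density * posterior$h
  s_mean <- sum(posterior$s * mass) + posterior$atom_weight * posterior$atom_s
  s_median <- posterior_median(posterior$s, mass, posterior$atom_weight,
                               posterior$atom_s, posterior$h)
  tibble::tibble(s_mean = s_mean, s_median = s_median,
                 f_mean = posterior$f_mean)
}

# atom-aware inverse cdf at probability 1/2
posterior_median <- function(s, mass, atom_w, atom_s, h) {
  ev <- c(s - 1e-12, atom_s)          # insert the atom in s-order
  mv <- c(mass, atom_w)
  o <- order(ev)
  cs <- cumsum(mv[o])
  i <- which(cs >= 0.5)[1]
  if (is.na(i)) return(s[length(s)])
  if (abs(ev[o][i] - atom_s) < 1e-9 && mv[o][i] == atom_w) return(atom_s)
  # within a lattice cell, interpolate linearly through the cell mass
  prev <- if (i > 1) cs[i - 1] else 0
  ev[o][i] - h / 2 + h * (0.5 - prev) / mv[o][i]
}

#' Naive log fold-change
#'
#' The plug-in estimator \eqn{s_{\mathrm{naive}} = \ln(n'/n)}; undefined
#' (NA) when either count is zero. Over-estimates the magnitude of
#' fold-changes for small clones, where count noise dominates.
#'
#' @param n,n_prime Count vectors.
#' @return Numeric vector; `NA` where a count is zero.
#' @export
naive_log_fold_change <- function(n, n_prime) {
  out <- rep(NA_real_, length(n))
  ok <- n > 0 & n_prime > 0
  out[ok] <- log(n_prime[ok] / n[ok])
  out
}

#' Detect responding clones
#'
#' Per-clone posterior calls from the fitted models: a clone is called
#' `expanded` when \eqn{P(s \le 0 \mid n, n') <} `threshold`, `contracted`
#' when \eqn{P(s \ge 0 \mid n, n') <} `threshold`, else `unresolved`. Ties
#' at the threshold are not significant. Posteriors are computed once per
#' unique count pair; the decision boundary is a monotone staircase in
#' \eqn{(n, n')}.
#'
#' @param tab A [pair_table()] across two time points.
#' @param null A `null_fit` or `list(prior=, model=)`.
#' @param exp_prior A fitted [expansion_prior()] (with solved `s0`), or an
#'   `expansion_fit` (whose cache is then reused).
#' @param threshold Posterior-probability threshold (default 0.025).
#' @inheritParams pair_likelihood_expansion
#' @return A tibble with one row per clone: `clone_id`, `n`, `n_prime`,
#'   `s_naive`, `s_mean`, `s_median`, `p_null_expand`, `p_null_contract`,
#'   `f_mean`, `call`.
#' @export
detect_responding <- function(tab, null = NULL, exp_prior, threshold = 0.025,
                              s_max = 12, step = 0.05) {
  stopifnot(inherits(tab, "pair_table"))
  if (inherits(exp_prior, "expansion_fit")) {
    fit <- exp_prior
    ca <- fit$cache
    same <- identical(ca$pairs, pt_pairs(tab))
    if (!same) ca <- expansion_cache(tab, null %||% list(prior = ca$prior, model = ca$model),
                                     s_max = ca$s_max, step = ca$step)
    ep <- fit$prior
  } else {
    ca <- expansion_cache(tab, null, s_max = s_max, step = step)
    ep <- exp_prior
  }
  po <- cache_posteriors(ca, ep)
  mass <- po$cont
  s_mean <- as.numeric(mass %*% po$s) + po$atom * po$atom_s
  s_med <- vapply(seq_len(nrow(mass)), function(k) {
    posterior_median(po$s, mass[k, ], po$atom[k], po$atom_s, ca$h)
  }, numeric(1))
  p_exp <- pmin(1, post_p_le(po, 0, include_atom = TRUE))
  p_con <- pmin(1, post_p_ge(po, 0, include_atom = TRUE))
  per_pair <- tibble::tibble(
    n = ca$pairs$n, n_prime = ca$pairs$n_prime,
    s_mean = s_mean, s_median = s_med,
    p_null_expand = p_exp, p_null_contract = p_con, f_mean = po$f_mean
  )
  out <- dplyr::left_join(
    tibble::tibble(clone_id = tab$clone_id, n = tab$n, n_prime = tab$n_prime),
    per_pair, by = c("n", "n_prime")
  )
  out$s_naive <- naive_log_fold_change(out$n, out$n_prime)
  out$call <- dplyr::case_when(
    out$p_null_expand < threshold ~ "expanded",
    out$p_null_contract < threshold ~ "contracted",
    TRUE ~ "unresolved"
  )
  dplyr::select(out, "clone_id", "n", "n_prime", "s_naive", "s_mean",
                "s_median", "p_null_expand", "p_null_contract", "f_mean",
                "call")
}

#' Overlap between two clone lists
#'
#' Jaccard index \eqn{|A \cap B| / |A \cup B|}; 0 for two empty lists by
#' convention. Used to assess the robustness of responding-clone lists to
#' uncertainty in the expansion-prior parameters.
#'
#' @param list_a,list_b Character vectors of clone ids.
#' @return A number in \eqn{[0, 1]}.
#' @export
list_overlap <- function(list_a, list_b) {
  a <- unique(list_a); b <- unique(list_b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}
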