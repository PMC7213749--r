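# Shared fixtures, built once per test run and cached. All synthetic data
# is generated in code under fixed seeds; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# mouse-scale same-day replicate pair, Poisson noise
fx_mouse_null_tab <- function() fixture("mouse_null_tab", function() {
  sample_null_pair(preset_config("mouse", seed = 11))
})

fx_true_null_mouse <- function() {
  list(prior = clone_size_prior(2, N = 1e6), model = noise_model("poisson"))
}

fx_mouse_null_fit <- function() fixture("mouse_null_fit", function() {
  fit_null(fx_mouse_null_tab(), "poisson")
})

# deep-mouse two-time-point pair with known responders (regular fit regime)
fx_exp_tab <- function() fixture("exp_tab", function() {
  ep <- expansion_prior("asym_exp", alpha = 0.01, sbar = 1)
  sample_expansion_pair(
    simulation_config(N = 1e6, nu = 2, n_read = 1e5, expansion = ep, seed = 63)
  )
})

fx_exp_fit <- function() fixture("exp_fit", function() {
  fit_expansion(fx_exp_tab(), fx_true_null_mouse(), family = "asym_exp")
})

# two-step-noise replicate pair at reduced repertoire scale
fx_nbp_noise <- function() noise_model("negbin_poisson", a = 0.7, gamma = 1.1, M = 1e5)

fx_nbp_tab <- function() fixture("nbp_tab", function() {
  sample_null_pair(simulation_config(N = 1e5, nu = 2, noise = fx_nbp_noise(),
                                     efficiency = 0.5, seed = 5))
})

# numerical quadrature of g(f) against the clone-size prior, in ln f
quad_lnf <- function(g, prior, rel.tol = 1e-11) {
  stats::integrate(function(lf) {
    f <- exp(lf)
    g(f) * clone_density(f, prior) * f
  }, log(prior$f_min), 0, rel.tol = rel.tol, subdivisions = 400L)$value
}
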