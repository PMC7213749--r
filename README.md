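# clonexpand

Bayesian detection of clonal expansion from immune-repertoire sequencing.

Longitudinal repertoire sequencing (RepSeq) tracks T-cell clonotypes by
their molecule (UMI) counts across samples. Deciding whether a clone truly
expanded between two time points is confounded by sampling, library
preparation and expression noise: count ratios n′/n fluctuate wildly even
between same-day replicates. `clonexpand` disentangles the two by

1. **calibrating the noise on same-day replicates** — jointly fitting a
   power-law clone-size prior ρ(f) = C f^(−ν) on [f_min, 1) and an explicit
   noise model P(n | f) (Poisson; negative binomial with variance
   n̄ + a·n̄^γ; or a two-step negative-binomial-to-Poisson law through the
   latent cell count m) by maximizing the likelihood of observed count pairs

       P(n, n′) = ∫ df ρ(f) P(n | f) P(n′ | f),

   conditioned on the clone being observed (n + n′ > 0) and subject to the
   normalization constraint N⟨f⟩ = 1 with N = N_obs / (1 − P(0,0));

2. **learning an expansion prior from two time points** — an
   empirical-Bayes spike-and-slab prior on the log fold-change
   s = ln(f′/f),

       ρ_s(s) = (1 − α) δ(s − s₀) + α ρ_exp(s − s₀),

   with responding fraction α, effect-size scale s̄, and a global shift s₀
   fixed by the equal-repertoire-size constraint Z′ = Z;

3. **calling responding clones from per-clone posteriors** —

       ρ(s | n, n′) ∝ ρ_s(s) ∫ df ρ(f) P(n | f) P(n′ | f·e^s),

   a clone is called expanded when P_null = P(s ≤ 0 | n, n′) < 0.025.

The package also estimates Hill diversities D_β of the full repertoire
(species richness, Shannon, Simpson) with Monte-Carlo error propagation,
and ships an exact synthetic-data generator (including a
quadrant-conditioned sampler that never instantiates the unobserved
clones), so the whole pipeline is testable end to end without external
data.

## Worked example

```r
library(clonexpand)

# same-day replicates from a mouse-sized repertoire (1e6 clones, 1e4 reads)
reps <- sample_null_pair(preset_config("mouse", seed = 11))
null_fit <- fit_null(reps, "poisson")
null_fit
#> <null_fit>  poisson noise, mean normalization
#>   theta:  nu=1.994, log10_f_min=-7.345
#>   avg conditioned log-lik = -1.490043   N_obs = 8595   N = 1.25e+06   Z = 1.0229

# two time points with 1% of clones expanding (scale sbar = 1)
ep  <- expansion_prior("asym_exp", alpha = 0.01, sbar = 1)
tab <- sample_expansion_pair(preset_config("mouse", expansion = ep, seed = 21))
exp_fit <- fit_expansion(tab, null_fit, family = "asym_exp")
exp_fit
#> <expansion_fit>  asym_exp: alpha = 0.02247, sbar = 0.8523, s0 = -0.05771
#>   avg conditioned log-lik = -1.490263   N_obs = 10336

calls <- detect_responding(tab, exp_prior = exp_fit)
table(calls$call)
#>   expanded unresolved
#>          4      10332
```

The null fit recovers the generating exponent ν = 2 and repertoire size
N = 10⁶ from the replicate pair alone; the expansion fit recovers
(α, s̄) near the generating (0.01, 1) — single realizations scatter along
the diagonal likelihood ridge in (α, s̄), whose product is much better
determined than either factor. `tidy()`/`glance()` give tabular summaries,
`autoplot()` draws the marginal count fit, the likelihood surface and
posteriors, and `plot_count_pairs()` shows calls in (n, n′) space.

A command-line interface wrapping the same functions
(`simulate`, `infer-null`, `infer-expansion`, `detect`, `diversity`) is
installed at `system.file("cli", "clonexpand", package = "clonexpand")`.

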