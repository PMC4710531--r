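# Shared test fixtures: default parameters are calibrated once (quadrature at
# construction), so reuse a single object across tests.
test_params <- model_parameters()

# Tight-tolerance parameter set for ODE-vs-closed-form fidelity checks.
tight_ode_params <- model_parameters(ode_rtol = 1e-10, ode_atol = 1e-12)

# The two distribution specs the model ships with.
clutch_spec <- trunc_lognormal_spec(4.11, 0.96, 1, 317)
interval_spec <- trunc_lognormal_spec(1.21, 0.57, 1, 25)

# Truncated-lognormal CDF written independently of the package (oracle).
oracle_trunc_cdf <- function(q, mu, sigma, lower, upper) {
  pl <- plnorm(lower, mu, sigma)
  pu <- plnorm(upper, mu, sigma)
  pmin(pmax((plnorm(q, mu, sigma) - pl) / (pu - pl), 0), 1)
}

# Small control-like cohort specs (three tanks of four females).
make_group_specs <- function(c_vtg = 0.1, n_groups = 3, per_group = 4) {
  specs <- list()
  for (g in seq_len(n_groups)) {
    for (f in seq_len(per_group)) {
      specs[[length(specs) + 1L]] <-
        fish_spec(sprintf("g%df%d", g, f), c_vtg, group_id = sprintf("g%d", g))
    }
  }
  specs
}
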