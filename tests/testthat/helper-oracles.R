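# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# exp(z^2) erfc(z) by adaptive quadrature of the defining integral:
# erfcx(z) = 2/sqrt(pi) * int_0^inf exp(-u^2 - 2 z u) du  (t = z + u).
# Stable for all z >= 0 because the integrand never involves exp(z^2).
erfcx_quadrature <- function(z) {
  vapply(z, function(zi) {
    2 / sqrt(pi) *
      integrate(function(u) exp(-u^2 - 2 * zi * u), 0, Inf,
                rel.tol = 1e-13)$value
  }, numeric(1))
}

survival_quadrature <- function(x) erfcx_quadrature(sqrt(x))

# Forward two-pool isotope mixing: given an exchangeable pool e_star of
# natural-composition Cu (mg/kg) and a 65-enriched spike (spike mg/kg,
# counted as moles of 65Cu = spike/am_65, with its 0.5% 63Cu companion on
# top), return the measured 63/65 amount ratio of the mixture.
mix_ir_meas <- function(e_star, spike, ir_nat = 2.2435,
                        ir_sp = 0.5 / 99.5, am_nat = 63.546,
                        am_65 = 64.928) {
  mol_nat <- e_star / am_nat
  n63_nat <- mol_nat * ir_nat / (1 + ir_nat)
  n65_nat <- mol_nat / (1 + ir_nat)
  n65_sp <- spike / am_65
  n63_sp <- ir_sp * n65_sp
  (n63_nat + n63_sp) / (n65_nat + n65_sp)
}

# noisy synthetic dataset shorthand
make_dataset <- function(n, seed, noise_sd = 0.02,
                         params = aging_params(), ...) {
  soils <- generate_soils(n, seed = seed, ...)
  simulate_observations(soils, params, noise_sd, seed = seed + 5000)
}
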