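# Shared fixtures for the suite. The segmentation-clock reference frequency
# (137.5-min period) is used throughout.
W_CLOCK <- 0.0457

# circular distance |wrap(a - b)|
circ_dist <- function(a, b) abs(wrap_phase(a - b))

# latent table with fixed initial differences (equal frequencies):
# phi_a0 = d0 (A ahead for d0 in (0, pi)), phi_b0 = 0
stratified_latent <- function(d0s, omega = W_CLOCK) {
  data.frame(triplet = seq_along(d0s),
             period_a = 2 * pi / omega, period_b = 2 * pi / omega,
             omega_a = omega, omega_b = omega,
             phi_a0 = d0s, phi_b0 = 0)
}

# final wrapped phase difference b - a of a pair simulation
final_diff <- function(sim) {
  n <- length(sim$a$times)
  wrap_phase(sim$b$phases[n] - sim$a$phases[n])
}
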