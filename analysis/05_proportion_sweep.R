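#!/usr/bin/env Rscript
# Unequal mixing proportions: under rectified coupling an ahead minority
# still imposes its phase on the mixed ensemble; under Kuramoto the majority
# dominates. Run at both the two-subpopulation mean-field level and with an
# explicit 16-oscillator ensemble.
suppressPackageStartupMessages(library(rekusync))
dir.create("results", showWarnings = FALSE)

w <- 0.0457
cfg <- sim_config(dt = 0.1, t_end = 600)
lat <- data.frame(triplet = 1, period_a = 2 * pi / w, period_b = 2 * pi / w,
                  omega_a = w, omega_b = w, phi_a0 = 1.2, phi_b0 = 0)

rows <- list()
for (fam in c("reku_plus", "kuramoto")) {
  for (p in seq(0.1, 0.9, by = 0.2)) {
    r <- run_pipeline(cohort = cohort_params(mix_fraction = p, seed = 1),
                      model = coupling_model(fam, c = 0.02), latent = lat)
    rows[[paste(fam, p)]] <- data.frame(
      model = fam, mix_fraction_ahead = p,
      outcome = r$records$outcome,
      dist_to_ahead = abs(r$records$y), dist_to_behind = abs(r$records$x))
  }
}
tab <- do.call(rbind, rows)
rownames(tab) <- NULL
write.csv(tab, "results/proportion_sweep.csv", row.names = FALSE)
print(tab)

# explicit ensemble: 4 ahead vs 12 behind oscillators
specs <- c(lapply(1:4, function(i) oscillator_spec(w, 1.2, "A")),
           lapply(1:12, function(i) oscillator_spec(w, 0, "B")))
for (fam in c("reku_plus", "kuramoto")) {
  sims <- simulate_ensemble(specs, coupling_model(fam, c = 0.02), cfg)
  finals <- vapply(sims, function(s) s$phases[length(s$phases)], numeric(1))
  coll <- Arg(mean(exp(1i * finals)))
  message(sprintf(
    "N=16, 25%% ahead, %-9s: collective phase %.3f rad from ahead, %.3f rad from weighted mean",
    fam, abs(wrap_phase(coll - (1.2 + w * 600))),
    abs(wrap_phase(coll - (0.25 * 1.2 + w * 600)))))
}
message("wrote results/proportion_sweep.csv")
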