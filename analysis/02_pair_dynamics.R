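#!/usr/bin/env Rscript
# Contrasts phase averaging (Kuramoto) with winner-takes-it-all (rectified
# coupling) for a coupled pair at the segmentation-clock frequency.
suppressPackageStartupMessages(library(rekusync))
dir.create("results", showWarnings = FALSE)

w <- 0.0457                       # rad/min, 137.5-min period
cfg <- sim_config(dt = 0.1, t_end = 600)
a <- oscillator_spec(w, 0, "A")
b <- oscillator_spec(w, 1, "B")   # B starts 1 rad ahead

runs <- list(
  kuramoto = coupling_model("kuramoto", c = 0.02),
  reku_plus = coupling_model("reku_plus", c = 0.02),
  reku_minus = coupling_model("reku_minus", c = 0.02)
)
tab <- do.call(rbind, lapply(names(runs), function(nm) {
  s <- simulate_pair(a, b, runs[[nm]], cfg)
  keep <- seq(1, length(s$a$times), by = 100)  # 10-min resolution output
  data.frame(model = nm, time_min = s$a$times[keep],
             phi_a = s$a$phases[keep], phi_b = s$b$phases[keep],
             dphi_wrapped = wrap_phase(s$b$phases[keep] - s$a$phases[keep]))
}))
write.csv(tab, "results/pair_dynamics.csv", row.names = FALSE)

for (nm in names(runs)) {
  sub <- tab[tab$model == nm, ]
  final <- sub[nrow(sub), ]
  message(sprintf(
    "%-10s final wrapped diff %+.4f rad; A moved %+.3f rad, B moved %+.3f rad rel. uncoupled",
    nm, final$dphi_wrapped, final$phi_a - w * 600, final$phi_b - 1 - w * 600))
}
message("wrote results/pair_dynamics.csv")
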