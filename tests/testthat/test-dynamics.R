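cfg600 <- sim_config(dt = 0.1, t_end = 600)

test_that("uncoupled oscillators advance exactly linearly", {
  a <- oscillator_spec(W_CLOCK, 0.3)
  b <- oscillator_spec(W_CLOCK * 1.02, -1.1)
  s <- simulate_pair(a, b, coupling_model("kuramoto", c = 0), cfg600)
  expect_lt(max(abs(s$a$phases - (0.3 + W_CLOCK * s$a$times))), 1e-10)
  expect_lt(max(abs(s$b$phases - (-1.1 + W_CLOCK * 1.02 * s$b$times))), 1e-10)
})

test_that("equal-frequency Kuramoto pair conserves the phase sum and meets at the mean", {
  a <- oscillator_spec(W_CLOCK, 0)
  b <- oscillator_spec(W_CLOCK, 1)
  s <- simulate_pair(a, b, coupling_model("kuramoto", c = 0.02), cfg600)
  n <- length(s$a$times)
  expect_lt(max(abs(s$a$phases + s$b$phases - 2 * W_CLOCK * s$a$times - 1)),
            1e-8)
  # in the rotating frame both converge to the initial mean phase 0.5
  expect_lt(abs(s$a$phases[n] - W_CLOCK * 600 - 0.5), 1e-6)
  expect_lt(abs(s$b$phases[n] - W_CLOCK * 600 - 0.5), 1e-6)
})

test_that("weakly coupled identical oscillators contract monotonically", {
  # classic phase-averaging picture: omega = 0.0457, c = 0.004
  s <- simulate_pair(oscillator_spec(0.0457, -2.0),
                     oscillator_spec(0.0457, 0.8),
                     coupling_model("kuramoto", c = 0.004), cfg600)
  d <- abs(wrap_phase(s$b$phases - s$a$phases))
  expect_true(all(diff(d) < 0))
})

test_that("rectified coupling leaves the leader untouched while the lagger converges", {
  # H+ : B starts 1 rad ahead and must win without moving
  a <- oscillator_spec(W_CLOCK, 0)
  b <- oscillator_spec(W_CLOCK, 1)
  s <- simulate_pair(a, b, coupling_model("reku_plus", c = 0.02), cfg600)
  expect_lt(max(abs(s$b$phases - (1 + W_CLOCK * s$b$times))), 1e-9)
  expect_lt(abs(final_diff(s)), 1e-4)
  d <- abs(wrap_phase(s$b$phases - s$a$phases))
  expect_true(all(diff(d) <= 1e-12))
  # H- : mirrored, the lagging oscillator is untouched and wins
  sm <- simulate_pair(a, b, coupling_model("reku_minus", c = 0.02), cfg600)
  expect_lt(max(abs(sm$a$phases - W_CLOCK * sm$a$times)), 1e-9)
  expect_lt(abs(final_diff(sm)), 1e-4)
})

test_that("antiphase is a preserved (unstable) fixed point for odd couplings", {
  s <- simulate_pair(oscillator_spec(W_CLOCK, 0),
                     oscillator_spec(W_CLOCK, pi),
                     coupling_model("kuramoto", c = 0.02),
                     sim_config(dt = 0.1, t_end = 300))
  expect_lt(max(abs(wrap_phase(s$b$phases - s$a$phases - pi))), 1e-8)
})

test_that("RK4 trajectories are converged at the default step", {
  a <- oscillator_spec(W_CLOCK, 0.4)
  b <- oscillator_spec(W_CLOCK * 1.01, -0.9)
  for (m in list(coupling_model("kuramoto", c = 0.02),
                 coupling_model("kuramoto_sakaguchi", alpha = 1, c = 0.02),
                 coupling_model("continuous_reku", beta = -5, c = 0.02))) {
    s1 <- simulate_pair(a, b, m, cfg600)
    s2 <- simulate_pair(a, b, m, sim_config(dt = 0.05, t_end = 600))
    expect_lt(abs(s1$a$phases[length(s1$a$phases)] -
                  s2$a$phases[length(s2$a$phases)]), 1e-7)
  }
  expect_error(
    simulate_pair(a, b, coupling_model("kuramoto"),
                  sim_config(dt = 10, t_end = 100)),
    "too coarse")
})

test_that("the integrator agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  a <- oscillator_spec(W_CLOCK, 0.2)
  b <- oscillator_spec(W_CLOCK * 1.015, -2.4)
  m <- coupling_model("kuramoto_sakaguchi", alpha = -0.7, c = 0.02)
  s <- simulate_pair(a, b, m, cfg600)
  rhs <- function(t, y, p) {
    list(c(W_CLOCK + 0.02 * (sin(wrap_phase(y[2] - y[1]) - 0.7) - sin(-0.7)),
           W_CLOCK * 1.015 +
             0.02 * (sin(wrap_phase(y[1] - y[2]) - 0.7) - sin(-0.7))))
  }
  ode <- deSolve::ode(c(0.2, -2.4), seq(0, 600, by = 0.1), rhs, NULL,
                      method = "ode45")
  n <- length(s$a$times)
  expect_lt(abs(s$a$phases[n] - ode[nrow(ode), 2]), 1e-6)
  expect_lt(abs(s$b$phases[n] - ode[nrow(ode), 3]), 1e-6)
})

test_that("stochastic integration is seed-reproducible and unbiased for c=0", {
  a <- oscillator_spec(W_CLOCK, 0)
  b <- oscillator_spec(W_CLOCK, 1)
  cfgn <- sim_config(dt = 0.1, t_end = 200, noise_sd = 0.05, seed = 7)
  s1 <- simulate_pair(a, b, coupling_model("kuramoto", c = 0), cfgn)
  s2 <- simulate_pair(a, b, coupling_model("kuramoto", c = 0), cfgn)
  expect_identical(s1$a$phases, s2$a$phases)
  # diffusion scale: final-phase SD ~ noise_sd * sqrt(t)
  expect_lt(abs(s1$a$phases[length(s1$a$phases)] - W_CLOCK * 200),
            5 * 0.05 * sqrt(200))
})

test_that("mean-field ensembles reduce to the pair at N=2 and keep symmetric states", {
  a <- oscillator_spec(W_CLOCK, 0.3)
  b <- oscillator_spec(W_CLOCK, 1.5)
  m <- coupling_model("continuous_reku", beta = -5, c = 0.02)
  sp <- simulate_pair(a, b, m, cfg600)
  se <- simulate_ensemble(list(a, b), m, cfg600)
  expect_lt(max(abs(se[[1]]$phases - sp$a$phases)), 1e-12)
  expect_lt(max(abs(se[[2]]$phases - sp$b$phases)), 1e-12)
  # identical initial phases stay identical: KOP stays 1
  specs <- lapply(1:6, function(i) oscillator_spec(W_CLOCK, 0.9))
  ss <- simulate_ensemble(specs, coupling_model("kuramoto", c = 0.02),
                          sim_config(dt = 0.1, t_end = 100))
  phm <- do.call(cbind, lapply(ss, `[[`, "phases"))
  expect_true(all(synchrony_over_time(phm)$kop == 1))
  expect_error(simulate_ensemble(list(), m, cfg600), "empty")
})

test_that("an ahead minority wins under rectified coupling but not under Kuramoto", {
  specs <- c(lapply(1:4, function(i) oscillator_spec(W_CLOCK, 1.2, "A")),
             lapply(1:12, function(i) oscillator_spec(W_CLOCK, 0, "B")))
  ahead_unc <- 1.2 + W_CLOCK * 600
  wmean <- 0.25 * 1.2 + W_CLOCK * 600
  for (fam in c("reku_plus", "kuramoto")) {
    sims <- simulate_ensemble(specs, coupling_model(fam, c = 0.02), cfg600)
    finals <- vapply(sims, function(s) s$phases[length(s$phases)],
                     numeric(1))
    coll <- Arg(mean(exp(1i * finals)))
    if (fam == "reku_plus") {
      expect_lt(circ_dist(coll, ahead_unc), 0.1)
    } else {
      expect_lt(circ_dist(coll, wmean), 0.05)
      expect_gt(circ_dist(coll, ahead_unc), 0.5)
    }
  }
})

test_that("pulsed dynamics reduce to the averaged effective coupling when weak", {
  R <- asymmetric_response_fn()
  S <- pulse_signal_fn(kappa = 200)
  a <- oscillator_spec(W_CLOCK, 0.2)
  b <- oscillator_spec(W_CLOCK, 1.2)
  cw <- 0.1 * W_CLOCK
  sp <- simulate_pair_pulsed(a, b, R, S, cw, cfg600)
  expect_lt(max(abs(diff(diff(sp$a$times)))), 1e-9)  # recorded on cfg grid
  sa <- simulate_pair(a, b, as_sampled_model(R, S, c = cw), cfg600)
  expect_lt(max(abs(wrap_phase(sp$b$phases - sp$a$phases) -
                    wrap_phase(sa$b$phases - sa$a$phases))), 0.05)
  s0 <- simulate_pair_pulsed(a, b, R, S, 0, cfg600)
  expect_lt(max(abs(s0$a$phases - (0.2 + W_CLOCK * s0$a$times))), 1e-10)
})

test_that("strong pulsed coupling yields winner-takes-it-all only for small shifts", {
  R <- sinusoidal_response_fn()
  S <- pulse_signal_fn(kappa = 200)
  cs <- 10 * W_CLOCK
  outcome_dist <- function(d0) {
    s <- simulate_pair_pulsed(oscillator_spec(W_CLOCK, 0),
                              oscillator_spec(W_CLOCK, d0), R, S, cs, cfg600)
    i <- which.min(abs(s$a$times - 400))
    mix <- Arg(0.5 * exp(1i * s$a$phases[i]) + 0.5 * exp(1i * s$b$phases[i]))
    y <- wrap_phase(d0 + W_CLOCK * 400 - mix)
    x <- wrap_phase(W_CLOCK * 400 - mix)
    min(abs(x), abs(y))
  }
  expect_lt(outcome_dist(0.3), 0.3)           # small shift: on an axis
  expect_gt(outcome_dist(2.9), 1.0)           # near antiphase: far from both
})

test_that("delayed coupling degenerates correctly and reduces to a phase-lagged model", {
  a <- oscillator_spec(W_CLOCK, 0.3)
  b <- oscillator_spec(W_CLOCK, 1.4)
  # tau = 0 is exactly the Kuramoto pair
  sd0 <- simulate_pair_delayed(a, b, c = 0.02, tau = 0, cfg600)
  sk <- simulate_pair(a, b, coupling_model("kuramoto", c = 0.02), cfg600)
  expect_lt(max(abs(sd0$a$phases - sk$a$phases),
                abs(sd0$b$phases - sk$b$phases)), 1e-10)
  # c = 0: linear phases for any delay
  sc0 <- simulate_pair_delayed(a, b, c = 0, tau = 20, cfg600)
  expect_lt(max(abs(sc0$a$phases - (0.3 + W_CLOCK * sc0$a$times))), 1e-10)
  expect_error(simulate_pair_delayed(a, b, c = 0.02, tau = -1, cfg600),
               ">= 0")
  # locked state matches the phase-lagged (alpha = -omega*tau) pair,
  # both for matched and mildly detuned frequencies
  cfgl <- sim_config(dt = 0.1, t_end = 2500)
  ks <- coupling_model("kuramoto_sakaguchi", c = 0.005,
                       alpha = -W_CLOCK * 20)
  for (bb in list(b, oscillator_spec(0.048, 1.4))) {
    sdel <- simulate_pair_delayed(a, bb, c = 0.005, tau = 20, cfgl)
    sks <- simulate_pair(a, bb, ks, cfgl)
    expect_lt(abs(final_diff(sdel) - final_diff(sks)), 0.05)
  }
})
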