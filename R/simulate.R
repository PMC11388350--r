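#' Oscillator specification
#'
#' Intrinsic angular frequency and initial phase of one phase oscillator,
#' tagged with the subpopulation it belongs to.
#'
#' @param omega Intrinsic angular frequency, rad/min; > 0. The mouse
#'   segmentation clock oscillates at about 0.0457 rad/min (137.5-min period).
#' @param phi0 Initial phase, rad; wrapped to (-pi, pi].
#' @param label Subpopulation tag, usually `"A"` or `"B"`.
#' @return An object of class `oscillator_spec`.
#' @export
oscillator_spec <- function(omega, phi0 = 0, label = "A") {
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) ||
      omega <= 0) {
    stop("`omega` must be a single finite value > 0", call. = FALSE)
  }
  if (!is.numeric(phi0) || length(phi0) != 1L || !is.finite(phi0)) {
    stop("`phi0` must be a single finite value", call. = FALSE)
  }
  structure(list(omega = omega, phi0 = wrap_phase(phi0),
                 label = as.character(label)),
            class = "oscillator_spec")
}

#' Simulation configuration
#'
#' Integration control shared by all simulators.
#'
#' @param dt Step size, min (default 0.1).
#' @param t_end Final time, min (default 600, the imaging span of a
#'   randomization experiment).
#' @param noise_sd Phase-diffusion intensity, rad/sqrt(min) (default 0; when
#'   positive the integrator switches from RK4 to Euler-Maruyama).
#' @param seed Integer seed used when `noise_sd > 0`.
#' @param delay_tau Coupling delay, min (delayed pair only).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.1, t_end = 600, noise_sd = 0, seed = NULL,
                       delay_tau = NULL) {
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (!is.numeric(t_end) || t_end < dt) {
    stop("`t_end` must be >= `dt`", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  structure(list(dt = dt, t_end = t_end, noise_sd = noise_sd, seed = seed,
                 delay_tau = delay_tau),
            class = "sim_config")
}

#' Phase trajectory container
#'
#' @param times Time grid, min (uniform, strictly increasing).
#' @param phases Unwrapped phases, rad.
#' @param meta Named list of identity metadata (label, omega, ...).
#' @return An object of class `phase_series`.
#' @export
phase_series <- function(times, phases, meta = list()) {
  check_uniform_times(times)
  if (length(phases) != length(times) || any(!is.finite(phases))) {
    stop("`phases` must be finite and match `times`", call. = FALSE)
  }
  structure(list(times = times, phases = phases, meta = meta),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series: %d samples, t in [%g, %g] min%s>\n",
              length(x$times), x$times[1L], x$times[length(x$times)],
              if (!is.null(x$meta$label)) paste0(", label ", x$meta$label)
              else ""))
  invisible(x)
}

#' @export
as.data.frame.phase_series <- function(x, ...) {
  data.frame(time_min = x$times,
             oscillator_id = x$meta$id %||% NA_character_,
             label = x$meta$label %||% NA_character_,
             phase_rad_unwrapped = x$phases)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared fixed-step driver. `f(phi)` returns the full phase velocity vector.
# RK4 when noise_sd = 0, Euler-Maruyama otherwise (independent noise per
# oscillator, one stream from cfg$seed).
integrate_phases <- function(omega, phi0, f, cfg) {
  min_period <- 2 * pi / max(omega)
  if (cfg$dt >= min_period / 20) {
    stop(sprintf(
      "dt = %g min is too coarse for the shortest period %.3g min (need dt < period/20)",
      cfg$dt, min_period), call. = FALSE)
  }
  h <- cfg$dt
  n <- floor(cfg$t_end / h + 1e-9)
  times <- seq(0, by = h, length.out = n + 1L)
  m <- length(phi0)
  out <- matrix(NA_real_, n + 1L, m)
  out[1L, ] <- phi <- phi0
  if (cfg$noise_sd > 0) {
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    sq <- cfg$noise_sd * sqrt(h)
    for (k in seq_len(n)) {
      phi <- phi + f(phi) * h + stats::rnorm(m, 0, sq)
      out[k + 1L, ] <- phi
    }
  } else {
    for (k in seq_len(n)) {
      k1 <- f(phi)
      k2 <- f(phi + h / 2 * k1)
      k3 <- f(phi + h / 2 * k2)
      k4 <- f(phi + h * k3)
      phi <- phi + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      out[k + 1L, ] <- phi
    }
  }
  list(times = times, phases = out)
}

#' Simulate a mean-field coupled ensemble
#'
#' Integrates phi_i' = omega_i + (c / (N - 1)) * sum_{j != i} H(phi_j - phi_i)
#' under all-to-all coupling. Normalizing by the number of partners keeps the
#' coupling strength `c` on the same scale for pairs and ensembles: N = 2
#' reduces identically to the pair equations. Subpopulation proportions are
#' encoded by how many specs carry each label.
#'
#' @param specs List of [oscillator_spec()]s (N >= 2).
#' @param model A [coupling_model()] of an averaged family (`custom_rs` only
#'   with a pre-convolved `sampled` H; see [as_sampled_model()]).
#' @param cfg A [sim_config()].
#' @return List of [phase_series()], one per oscillator, in input order.
#' @export
simulate_ensemble <- function(specs, model, cfg = sim_config()) {
  if (!length(specs)) stop("`specs` must not be empty", call. = FALSE)
  if (length(specs) < 2L) stop("need at least 2 oscillators", call. = FALSE)
  stopifnot(all(vapply(specs, inherits, logical(1L), "oscillator_spec")))
  omega <- vapply(specs, `[[`, numeric(1L), "omega")
  phi0 <- vapply(specs, `[[`, numeric(1L), "phi0")
  labels <- vapply(specs, `[[`, character(1L), "label")
  n_osc <- length(specs)
  cc <- model$c / (n_osc - 1L)
  H0 <- evaluate_coupling(model, 0)
  f <- function(phi) {
    d <- outer(-phi, phi, `+`)  # d[i, j] = phi_j - phi_i
    hv <- matrix(evaluate_coupling(model, as.vector(d)), n_osc, n_osc)
    omega + cc * (rowSums(hv) - H0)
  }
  sim <- integrate_phases(omega, phi0, f, cfg)
  lapply(seq_len(n_osc), function(i) {
    phase_series(sim$times, sim$phases[, i],
                 meta = list(id = i, label = labels[i], omega = omega[i],
                             phi0 = phi0[i]))
  })
}

#' Simulate a coupled pair under an averaged coupling function
#'
#' Integrates phi_A' = omega_A + c * H(phi_B - phi_A) and the symmetric
#' equation for B with fixed-step RK4 (Euler-Maruyama when `noise_sd > 0`).
#' Phase differences are wrapped to (-pi, pi] inside every stage evaluation.
#'
#' @param a,b [oscillator_spec()]s.
#' @param model A [coupling_model()] of an averaged family.
#' @param cfg A [sim_config()].
#' @return List with elements `a` and `b`, each a [phase_series()].
#' @export
simulate_pair <- function(a, b, model, cfg = sim_config()) {
  out <- simulate_ensemble(list(a, b), model, cfg)
  list(a = out[[1L]], b = out[[2L]])
}

#' Simulate a mixed-ensemble pair with unequal subpopulation weights
#'
#' Coarse-grained dynamics of a well-mixed two-subpopulation ensemble where a
#' fraction `p` of cells carries phase A:
#' phi_A' = omega_A + 2 c (1 - p) H(phi_B - phi_A),
#' phi_B' = omega_B + 2 c p H(phi_A - phi_B).
#' Each subpopulation feels the other in proportion to the other's abundance;
#' the factor 2 normalizes so `p = 0.5` reproduces the pair equations exactly.
#'
#' @param a,b [oscillator_spec()]s for subpopulations A and B.
#' @param model A [coupling_model()] of an averaged family.
#' @param mix_fraction Proportion of A cells, in [0, 1].
#' @param cfg A [sim_config()].
#' @return List with elements `a` and `b`, each a [phase_series()].
#' @export
simulate_mixture <- function(a, b, model, mix_fraction = 0.5,
                             cfg = sim_config()) {
  stopifnot(inherits(a, "oscillator_spec"), inherits(b, "oscillator_spec"))
  if (!is.numeric(mix_fraction) || mix_fraction < 0 || mix_fraction > 1) {
    stop("`mix_fraction` must be in [0, 1]", call. = FALSE)
  }
  p <- mix_fraction
  omega <- c(a$omega, b$omega)
  w <- 2 * model$c * c(1 - p, p)
  f <- function(phi) {
    omega + w * evaluate_coupling(model, c(phi[2L] - phi[1L],
                                           phi[1L] - phi[2L]))
  }
  sim <- integrate_phases(omega, c(a$phi0, b$phi0), f, cfg)
  list(a = phase_series(sim$times, sim$phases[, 1L],
                        meta = list(id = 1L, label = a$label,
                                    omega = a$omega, phi0 = a$phi0)),
       b = phase_series(sim$times, sim$phases[, 2L],
                        meta = list(id = 2L, label = b$label,
                                    omega = b$omega, phi0 = b$phi0)))
}

#' Simulate a pair under unaveraged pulsed coupling
#'
#' Integrates the signal/response dynamics without cycle averaging:
#' phi_A' = omega_A + c * R(phi_A) * S(phi_B) and symmetrically for B. Valid
#' for arbitrary coupling strength; in the strong-coupling regime (c of order
#' 10 * omega) the step size is refined internally so that the maximal phase
#' velocity advances less than 0.2 rad per substep, while output is still
#' recorded on the `cfg$dt` grid.
#'
#' @param a,b [oscillator_spec()]s.
#' @param response_fn Response function R(phi) of the receiving oscillator.
#' @param signal_fn Signal function S(phi) of the sending oscillator.
#' @param c Coupling strength, rad/min (>= 0).
#' @param cfg A [sim_config()] (deterministic path only).
#' @return List with elements `a` and `b`, each a [phase_series()].
#' @export
simulate_pair_pulsed <- function(a, b, response_fn, signal_fn, c,
                                 cfg = sim_config()) {
  stopifnot(inherits(a, "oscillator_spec"), inherits(b, "oscillator_spec"))
  if (!is.numeric(c) || c < 0) stop("`c` must be >= 0", call. = FALSE)
  grid <- seq(0, 2 * pi, length.out = 513L)[-513L]
  bound <- max(a$omega, b$omega) +
    c * max(abs(response_fn(grid))) * max(abs(signal_fn(grid)))
  nsub <- max(1L, ceiling(cfg$dt * bound / 0.2))
  omega <- c(a$omega, b$omega)
  f <- function(phi) {
    p <- phi %% (2 * pi)
    omega + c * c(response_fn(p[1L]) * signal_fn(p[2L]),
                  response_fn(p[2L]) * signal_fn(p[1L]))
  }
  sub_cfg <- cfg
  sub_cfg$dt <- cfg$dt / nsub
  sim <- integrate_phases(omega, c(a$phi0, b$phi0), f, sub_cfg)
  keep <- seq(1L, length(sim$times), by = nsub)
  list(a = phase_series(sim$times[keep], sim$phases[keep, 1L],
                        meta = list(id = 1L, label = a$label,
                                    omega = a$omega, phi0 = a$phi0)),
       b = phase_series(sim$times[keep], sim$phases[keep, 2L],
                        meta = list(id = 2L, label = b$label,
                                    omega = b$omega, phi0 = b$phi0)))
}

#' Simulate a pair with delayed sinusoidal coupling
#'
#' Integrates phi_A'(t) = omega_A + c * sin(phi_B(t - tau) - phi_A(t)) and the
#' symmetric equation, with constant pre-history phi(t < 0) = phi0 (oscillators
#' run uncoupled before mixing). The delayed value is read from a linearly
#' interpolated history buffer; when a stage time falls closer than `tau` to
#' the buffer head (only possible for tau < dt) the partner's current stage
#' value is used, which makes tau = 0 reduce exactly to the RK4 Kuramoto pair.
#'
#' @param a,b [oscillator_spec()]s.
#' @param c Coupling strength, rad/min (>= 0).
#' @param tau Delay, min (>= 0).
#' @param cfg A [sim_config()] (deterministic path only).
#' @return List with elements `a` and `b`, each a [phase_series()].
#' @export
simulate_pair_delayed <- function(a, b, c, tau, cfg = sim_config()) {
  stopifnot(inherits(a, "oscillator_spec"), inherits(b, "oscillator_spec"))
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0) {
    stop("`tau` must be a single finite value >= 0", call. = FALSE)
  }
  if (!is.numeric(c) || c < 0) stop("`c` must be >= 0", call. = FALSE)
  h <- cfg$dt
  min_period <- 2 * pi / max(a$omega, b$omega)
  if (h >= min_period / 20) {
    stop("dt too coarse for the shortest period (need dt < period/20)",
         call. = FALSE)
  }
  n <- floor(cfg$t_end / h + 1e-9)
  times <- seq(0, by = h, length.out = n + 1L)
  phiA <- phiB <- numeric(n + 1L)
  phiA[1L] <- a$phi0
  phiB[1L] <- b$phi0
  wA <- a$omega
  wB <- b$omega
  # history lookup on the filled grid; constant before t = 0
  lookup <- function(arr, q) {
    if (q <= 0) return(arr[1L])
    idx <- q / h
    i0 <- floor(idx + 1e-12)
    frac <- idx - i0
    arr[i0 + 1L] * (1 - frac) + arr[i0 + 2L] * frac
  }
  for (k in seq_len(n)) {
    t <- times[k]
    # stage 1 (time t): delayed arg t - tau <= t, always in the buffer
    dA1 <- lookup(phiB, t - tau)
    dB1 <- lookup(phiA, t - tau)
    k1A <- wA + c * sin(dA1 - phiA[k])
    k1B <- wB + c * sin(dB1 - phiB[k])
    # stage 2 (time t + h/2)
    sA <- phiA[k] + h / 2 * k1A
    sB <- phiB[k] + h / 2 * k1B
    if (tau >= h / 2) {
      dA2 <- lookup(phiB, t + h / 2 - tau)
      dB2 <- lookup(phiA, t + h / 2 - tau)
    } else {
      dA2 <- sB
      dB2 <- sA
    }
    k2A <- wA + c * sin(dA2 - sA)
    k2B <- wB + c * sin(dB2 - sB)
    # stage 3 (time t + h/2)
    sA <- phiA[k] + h / 2 * k2A
    sB <- phiB[k] + h / 2 * k2B
    if (tau < h / 2) {
      dA2 <- sB
      dB2 <- sA
    }
    k3A <- wA + c * sin(dA2 - sA)
    k3B <- wB + c * sin(dB2 - sB)
    # stage 4 (time t + h)
    sA <- phiA[k] + h * k3A
    sB <- phiB[k] + h * k3B
    if (tau >= h) {
      dA4 <- lookup(phiB, t + h - tau)
      dB4 <- lookup(phiA, t + h - tau)
    } else {
      dA4 <- sB
      dB4 <- sA
    }
    k4A <- wA + c * sin(dA4 - sA)
    k4B <- wB + c * sin(dB4 - sB)
    phiA[k + 1L] <- phiA[k] + h / 6 * (k1A + 2 * k2A + 2 * k3A + k4A)
    phiB[k + 1L] <- phiB[k] + h / 6 * (k1B + 2 * k2B + 2 * k3B + k4B)
  }
  list(a = phase_series(times, phiA,
                        meta = list(id = 1L, label = a$label, omega = wA,
                                    phi0 = a$phi0)),
       b = phase_series(times, phiB,
                        meta = list(id = 2L, label = b$label, omega = wB,
                                    phi0 = b$phi0)))
}
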