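#' Construct a coupling model
#'
#' A coupling model pairs a coupling-function family with its parameters. The
#' families cover the models compared in the segmentation-clock synchronization
#' analysis:
#' \describe{
#'   \item{`kuramoto`}{H(d) = sin(d); symmetric phase averaging.}
#'   \item{`kuramoto_sakaguchi`}{H(d) = sin(d + alpha) - sin(alpha); the
#'     frustration offset `alpha` tilts the response while keeping H(0) = 0.}
#'   \item{`reku_plus`}{H(d) = max(0, sin(d)); rectified Kuramoto, the
#'     oscillator ahead is untouched and pulls the one behind forward.}
#'   \item{`reku_minus`}{H(d) = min(0, sin(d)); mirrored rectification, the
#'     oscillator behind wins.}
#'   \item{`continuous_reku`}{a one-parameter family interpolating between the
#'     two rectified limits through the Kuramoto model at `beta = 0`. Under the
#'     default `ahead_wins_negative_beta` convention,
#'     H(d) = sin(d) * (1 - tanh(beta * d)), so beta -> -Inf approaches
#'     2 * max(0, sin(d)) (ahead wins) and beta -> +Inf approaches
#'     2 * min(0, sin(d)). `literal_eq9` evaluates
#'     sin(d) * (1 + tanh(beta * d)) instead, which mirrors the beta limits.}
#'   \item{`custom_rs`}{an unaveraged signal/response pair (S, R). Averaged
#'     simulation requires pre-convolving with [effective_coupling()]; see
#'     [as_sampled_model()].}
#' }
#' The phase-difference argument is always d = phi_other - phi_self, wrapped to
#' (-pi, pi] before evaluation, which makes every family 2*pi-periodic by
#' construction. The beta -> +/-Inf limits carry a factor 2 relative to the
#' plain rectified functions; this is deliberate and absorbed into `c`.
#'
#' @param family One of `"kuramoto"`, `"kuramoto_sakaguchi"`, `"reku_plus"`,
#'   `"reku_minus"`, `"continuous_reku"`, `"custom_rs"`.
#' @param c Coupling strength, rad/min; must be >= 0. Applied by the
#'   simulators, not by [evaluate_coupling()].
#' @param alpha Phase offset, rad (Kuramoto-Sakaguchi only).
#' @param beta Asymmetry parameter, dimensionless (continuous ReKu only).
#' @param response_fn,signal_fn Periodic function handles on [0, 2*pi)
#'   (`custom_rs` only).
#' @param convention Sign convention for continuous ReKu; see Details.
#' @param sampled Optional [sampled_function()] giving a pre-convolved
#'   effective coupling for a `custom_rs` model.
#' @return An object of class `coupling_model`.
#' @seealso [evaluate_coupling()], [effective_coupling()]
#' @export
coupling_model <- function(family = c("kuramoto", "kuramoto_sakaguchi",
                                      "reku_plus", "reku_minus",
                                      "continuous_reku", "custom_rs"),
                           c = 0.02, alpha = NULL, beta = NULL,
                           response_fn = NULL, signal_fn = NULL,
                           convention = c("ahead_wins_negative_beta",
                                          "literal_eq9"),
                           sampled = NULL) {
  family <- match.arg(family)
  convention <- match.arg(convention)
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 0) {
    stop("coupling strength `c` must be a single finite value >= 0",
         call. = FALSE)
  }
  if (family == "kuramoto_sakaguchi") {
    if (is.null(alpha) || !is.finite(alpha)) {
      stop("Kuramoto-Sakaguchi requires a finite `alpha`", call. = FALSE)
    }
  }
  if (family == "continuous_reku") {
    if (is.null(beta) || !is.finite(beta)) {
      stop("continuous ReKu requires a finite `beta`", call. = FALSE)
    }
  }
  if (family == "custom_rs" && is.null(sampled)) {
    if (!is.function(response_fn) || !is.function(signal_fn)) {
      stop("custom_rs requires `response_fn` and `signal_fn`", call. = FALSE)
    }
  }
  if (!is.null(sampled) && !inherits(sampled, "sampled_function")) {
    stop("`sampled` must be a sampled_function", call. = FALSE)
  }
  structure(
    list(family = family, c = c, alpha = alpha, beta = beta,
         response_fn = response_fn, signal_fn = signal_fn,
         convention = convention, sampled = sampled),
    class = "coupling_model"
  )
}

#' @export
print.coupling_model <- function(x, ...) {
  pars <- c(
    sprintf("c = %g", x$c),
    if (!is.null(x$alpha)) sprintf("alpha = %g", x$alpha),
    if (!is.null(x$beta)) sprintf("beta = %g (%s)", x$beta, x$convention),
    if (!is.null(x$sampled)) "pre-convolved H attached"
  )
  cat(sprintf("<coupling_model: %s | %s>\n", x$family,
              paste(pars, collapse = ", ")))
  invisible(x)
}

#' Evaluate a coupling function H at a phase difference
#'
#' Returns the dimensionless coupling value H(d) with d = phi_other - phi_self
#' wrapped to (-pi, pi] first. The coupling strength `c` is *not* applied here;
#' the simulators multiply by it.
#'
#' @param model A [coupling_model()].
#' @param dphi Phase difference(s), rad; finite.
#' @return Numeric vector of coupling values, same length as `dphi`.
#' @examples
#' evaluate_coupling(coupling_model("kuramoto"), pi / 2)          # 1
#' evaluate_coupling(coupling_model("reku_plus"), -pi / 2)        # 0
#' @export
evaluate_coupling <- function(model, dphi) {
  stopifnot(inherits(model, "coupling_model"))
  d <- wrap_phase(dphi)
  switch(
    model$family,
    kuramoto = sin(d),
    kuramoto_sakaguchi = sin(d + model$alpha) - sin(model$alpha),
    reku_plus = pmax(0, sin(d)),
    reku_minus = pmin(0, sin(d)),
    continuous_reku = {
      if (model$convention == "literal_eq9") {
        sin(d) * (1 + tanh(model$beta * d))
      } else {
        sin(d) * (1 - tanh(model$beta * d))
      }
    },
    custom_rs = {
      if (is.null(model$sampled)) {
        stop(paste("custom_rs models have no closed-form H;",
                   "convolve with effective_coupling() first",
                   "(see as_sampled_model())"), call. = FALSE)
      }
      eval_sampled(model$sampled, d)
    }
  )
}

#' Construct a sampled periodic function
#'
#' Container for a 2*pi-periodic function sampled on a uniform grid in
#' [0, 2*pi), e.g. an effective coupling function produced by
#' [effective_coupling()].
#'
#' @param grid Phases in [0, 2*pi), strictly increasing, uniform.
#' @param values Finite function values at `grid`.
#' @return An object of class `sampled_function` with fields `grid`, `values`,
#'   `spacing`.
#' @export
sampled_function <- function(grid, values) {
  if (length(grid) < 2L || length(grid) != length(values)) {
    stop("`grid` and `values` must have equal length >= 2", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  if (grid[1L] < 0 || grid[length(grid)] >= 2 * pi) {
    stop("`grid` must lie in [0, 2*pi)", call. = FALSE)
  }
  spacing <- check_uniform_times(grid, "grid")
  structure(list(grid = grid, values = values, spacing = spacing),
            class = "sampled_function")
}

#' Evaluate a sampled periodic function by interpolation
#'
#' Periodic linear interpolation of a [sampled_function()] at arbitrary phases.
#'
#' @param sf A `sampled_function`.
#' @param phi Phases, rad (any finite values; reduced mod 2*pi).
#' @return Interpolated values.
#' @export
eval_sampled <- function(sf, phi) {
  stopifnot(inherits(sf, "sampled_function"))
  n <- length(sf$grid)
  p <- (phi - sf$grid[1L]) %% (2 * pi)
  p[p >= 2 * pi] <- 0  # float guard: %% can return the modulus itself
  idx <- p / sf$spacing
  i0 <- floor(idx)
  frac <- idx - i0
  i0 <- as.integer(i0) %% n
  i1 <- (i0 + 1L) %% n
  sf$values[i0 + 1L] * (1 - frac) + sf$values[i1 + 1L] * frac
}

#' Effective coupling function from signal and response functions
#'
#' Cycle-averages an unaveraged signal/response interaction into a single
#' coupling function of the phase difference,
#' H(d) = (1/2pi) * integral_0^2pi R(u) S(d + u) du,
#' evaluated by the trapezoid rule on a uniform periodic grid (spectrally
#' accurate for smooth periodic integrands).
#'
#' @param response_fn Response function R, evaluable on [0, 2*pi).
#' @param signal_fn Signal function S, evaluable on [0, 2*pi).
#' @param n_grid Number of grid points (>= 16; default 512).
#' @return A [sampled_function()] holding H on the grid.
#' @examples
#' H <- effective_coupling(sin, sin)
#' max(abs(H$values - cos(H$grid) / 2))  # ~1e-16: closed form cos(d)/2
#' @export
effective_coupling <- function(response_fn, signal_fn, n_grid = 512L) {
  if (!is.function(response_fn) || !is.function(signal_fn)) {
    stop("`response_fn` and `signal_fn` must be functions", call. = FALSE)
  }
  n_grid <- as.integer(n_grid)
  if (is.na(n_grid) || n_grid < 16L) {
    stop("`n_grid` must be >= 16", call. = FALSE)
  }
  u <- seq(0, 2 * pi, length.out = n_grid + 1L)[seq_len(n_grid)]
  R <- response_fn(u)
  if (any(!is.finite(R))) {
    stop(sprintf("response function non-finite at phase %.6g",
                 u[which(!is.finite(R))[1L]]), call. = FALSE)
  }
  H <- vapply(u, function(d) {
    S <- signal_fn((u + d) %% (2 * pi))
    if (any(!is.finite(S))) {
      stop(sprintf("signal function non-finite at phase %.6g",
                   ((u + d) %% (2 * pi))[which(!is.finite(S))[1L]]),
           call. = FALSE)
    }
    mean(R * S)
  }, numeric(1L))
  sampled_function(u, H)
}

#' Wrap a signal/response pair into an averaged coupling model
#'
#' Convenience: convolves R and S with [effective_coupling()] and returns a
#' `custom_rs` model carrying the sampled H, usable by [simulate_pair()] and
#' [simulate_ensemble()].
#'
#' @param response_fn,signal_fn Periodic functions on [0, 2*pi).
#' @param c Coupling strength, rad/min.
#' @param n_grid Convolution grid size.
#' @return A [coupling_model()] of family `custom_rs` with `sampled` set.
#' @export
as_sampled_model <- function(response_fn, signal_fn, c = 0.02,
                             n_grid = 512L) {
  H <- effective_coupling(response_fn, signal_fn, n_grid)
  coupling_model("custom_rs", c = c, response_fn = response_fn,
                 signal_fn = signal_fn, sampled = H)
}

#' Default pulsed-coupling signal function
#'
#' Narrow 2*pi-periodic pulse, exp(kappa * (cos(phi - center) - 1)): peak value
#' 1 at `center`, width ~ 1/sqrt(kappa). Stand-in for a sender that emits only
#' around one phase of its cycle.
#'
#' @param kappa Concentration (> 0); larger is narrower. Default 200
#'   (width about 0.07 rad, i.e. the sender is "on" for a few minutes per
#'   137-min cycle).
#' @param center Pulse phase, rad. Default 0 (the reporter peak).
#' @return A function of phase.
#' @export
pulse_signal_fn <- function(kappa = 200, center = 0) {
  force(kappa); force(center)
  function(phi) exp(kappa * (cos(phi - center) - 1))
}

#' Sinusoidal response function
#'
#' R(phi) = -sin(phi): the canonical non-rectified phase response (delayed
#' just after the peak, advanced just before it). Paired with a narrow pulse
#' this is the pulsed-coupling model used for model comparison: its
#' cycle-average is Kuramoto-like, and in the strong-coupling regime each
#' pulse resets the partner toward the sender's phase, which achieves
#' winner-takes-it-all only for small phase differences and diverges near
#' antiphase.
#'
#' @return A function of phase.
#' @export
sinusoidal_response_fn <- function() {
  function(phi) -sin(phi)
}

#' Default doubly asymmetric response function
#'
#' R(phi) = max(0, -sin(phi)): zero over half the cycle and single-signed
#' (positive) over the other half. Convolved with a narrow pulse at phase 0
#' this yields an effective coupling close to the rectified ahead-wins form
#' max(0, sin(d)) (up to the pulse mass).
#'
#' @return A function of phase.
#' @export
asymmetric_response_fn <- function() {
  function(phi) pmax(0, -sin(phi))
}

#' Serialize a sampled function to CSV
#'
#' Two columns: `phase_rad`, `value`.
#'
#' @param sf A [sampled_function()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sampled_function <- function(sf, path) {
  stopifnot(inherits(sf, "sampled_function"))
  utils::write.csv(data.frame(phase_rad = sf$grid, value = sf$values),
                   path, row.names = FALSE)
  invisible(path)
}
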