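#' Wrap a phase to (-pi, pi]
#'
#' Maps any finite phase onto the principal interval, keeping the boundary at
#' +pi (so `wrap_phase(pi)` and `wrap_phase(-pi)` both return `pi`). Every
#' phase-difference computation in the package wraps its argument with this
#' convention before evaluating a coupling function.
#'
#' @param phi Numeric vector of phases, radians.
#' @return Numeric vector of the same length, values in (-pi, pi].
#' @examples
#' wrap_phase(3 * pi / 2)  # -pi/2
#' wrap_phase(c(-pi, pi))  # both pi
#' @export
wrap_phase <- function(phi) {
  if (!is.numeric(phi)) {
    stop("`phi` must be numeric", call. = FALSE)
  }
  if (length(phi) && any(!is.finite(phi))) {
    stop("`phi` must be finite", call. = FALSE)
  }
  phi - 2 * pi * ceiling((phi - pi) / (2 * pi))
}

#' Unwrap a wrapped phase sequence
#'
#' Cumulative nearest-branch unwrapping: each successive jump is shifted by
#' the multiple of 2*pi that minimizes its magnitude. Inverse of wrapping for
#' series sampled densely enough that true steps stay below pi.
#'
#' @param phi Numeric vector of (possibly wrapped) phases, radians.
#' @return Numeric vector of unwrapped phases.
#' @export
unwrap_phase <- function(phi) {
  if (!is.numeric(phi)) {
    stop("`phi` must be numeric", call. = FALSE)
  }
  if (length(phi) < 2L) {
    return(phi)
  }
  d <- diff(phi)
  phi[1L] + c(0, cumsum(d - 2 * pi * round(d / (2 * pi))))
}

# Uniform-grid check shared by series containers; returns the common step.
check_uniform_times <- function(times, what = "times") {
  if (length(times) < 2L) {
    stop(sprintf("`%s` needs at least two samples", what), call. = FALSE)
  }
  d <- diff(times)
  if (any(d <= 0)) {
    stop(sprintf("`%s` must be strictly increasing", what), call. = FALSE)
  }
  if (max(d) - min(d) > 1e-8 * max(d)) {
    stop(sprintf("`%s` must lie on a uniform grid", what), call. = FALSE)
  }
  mean(d)
}
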