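#' Label which oscillator is ahead
#'
#' An oscillator is "ahead" when its wrapped phase lead over the other lies in
#' (0, pi). Near antiphase the label is experimentally meaningless, so leads
#' within `antiphase_eps` of pi (in absolute value) return `"ambiguous"`, as
#' does an exact tie.
#'
#' @param phi_a0,phi_b0 Phases of A and B at a common pre-synchronization
#'   reference time, rad.
#' @param antiphase_eps Ambiguity half-width around antiphase, rad
#'   (default 0.15).
#' @return `"A"`, `"B"`, or `"ambiguous"`.
#' @examples
#' label_ahead(0.5, 0)    # "A"
#' label_ahead(-3, 3)     # "A": wrap(-6) is about +0.283
#' @export
label_ahead <- function(phi_a0, phi_b0, antiphase_eps = 0.15) {
  d <- wrap_phase(phi_a0 - phi_b0)
  if (abs(d) > pi - antiphase_eps) return("ambiguous")
  if (d > 0) "A" else if (d < 0) "B" else "ambiguous"
}

#' Classify a synchronization outcome in the (behind - mix, ahead - mix) plane
#'
#' Computes the outcome coordinates `y = wrap(phi_ahead - phi_mix)` and
#' `x = wrap(phi_behind - phi_mix)` at the readout time and classifies the
#' triplet. The horizontal axis (y = 0) means the ahead oscillator won, the
#' vertical axis (x = 0) means the behind oscillator won, and the
#' anti-diagonal y = -x is phase averaging. Rules apply in priority order:
#' \enumerate{
#'   \item |x| <= tol and |y| <= tol: `degenerate_in_phase` (the ensembles
#'     ended so close that ahead/behind is meaningless);
#'   \item |y| <= tol: `ahead_wins`;
#'   \item |x| <= tol: `behind_wins`;
#'   \item |x + y| <= tol: `averaging`;
#'   \item otherwise `other`.
#' }
#'
#' @param phi_ahead,phi_behind,phi_mix Phases at the readout time, rad.
#' @param tol Tolerance band half-width, rad (> 0; default 0.3, set to exceed
#'   the ensemble-level phase-estimation error).
#' @return List with `x`, `y`, `outcome`.
#' @export
classify_outcome <- function(phi_ahead, phi_behind, phi_mix, tol = 0.3) {
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  y <- wrap_phase(phi_ahead - phi_mix)
  x <- wrap_phase(phi_behind - phi_mix)
  outcome <- if (abs(x) <= tol && abs(y) <= tol) {
    "degenerate_in_phase"
  } else if (abs(y) <= tol) {
    "ahead_wins"
  } else if (abs(x) <= tol) {
    "behind_wins"
  } else if (abs(x + y) <= tol) {
    "averaging"
  } else {
    "other"
  }
  list(x = x, y = y, outcome = outcome)
}

outcome_levels <- c("ahead_wins", "behind_wins", "averaging",
                    "degenerate_in_phase", "other", "ambiguous_antiphase")

#' Summarize a cohort of classified triplets
#'
#' Counts outcomes and computes the winner-takes-it-all fraction
#' (`ahead_wins` + `behind_wins` + `degenerate_in_phase`), the ahead-wins
#' fraction, and the mean distance to the nearest axis, min(|x|, |y|).
#' Triplets labeled `ambiguous_antiphase` are counted but excluded from the
#' fraction denominators and the axis-distance mean (near-antiphase starts
#' carry no usable ahead/behind label).
#'
#' @param records Data frame with columns `x`, `y`, `outcome`.
#' @return List with `n`, `n_unambiguous`, `counts` (named integer vector
#'   over all outcome classes), `fraction_wta`, `fraction_ahead_wins`,
#'   `mean_axis_distance`.
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || !nrow(records)) {
    stop("`records` must be a non-empty data frame", call. = FALSE)
  }
  stopifnot(all(c("x", "y", "outcome") %in% names(records)))
  counts <- table(factor(records$outcome, levels = outcome_levels))
  counts <- stats::setNames(as.integer(counts), outcome_levels)
  keep <- records$outcome != "ambiguous_antiphase"
  n_un <- sum(keep)
  wta <- counts[["ahead_wins"]] + counts[["behind_wins"]] +
    counts[["degenerate_in_phase"]]
  list(
    n = nrow(records),
    n_unambiguous = n_un,
    counts = counts,
    fraction_wta = if (n_un) wta / n_un else NA_real_,
    fraction_ahead_wins = if (n_un) counts[["ahead_wins"]] / n_un
                          else NA_real_,
    mean_axis_distance = if (n_un) {
      mean(pmin(abs(records$x[keep]), abs(records$y[keep])))
    } else NA_real_
  )
}
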