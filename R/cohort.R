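#' Cohort generator parameters
#'
#' Parameters of the synthetic randomization-assay cohort: each "triplet" is
#' one in-silico experiment with two reference ensembles (A, B) evolving
#' uncoupled and one mixed ensemble (AB) whose two subpopulations are coupled
#' by a chosen model. Defaults emulate the mouse segmentation-clock setting:
#' 137.5-min mean period (omega = 0.0457 rad/min) with a 1.5-min spread,
#' initial phases spanning the full circle with near-antiphase starts
#' excluded, a 1:1 mix, and 5 regions of interest (ROIs) per ensemble.
#'
#' @param n_triplets Number of triplets (default 32).
#' @param period_mean Mean period, min (default 137.5 = 2*pi/0.0457).
#' @param period_sd Period SD, min (default 1.5); draws truncated at +/- 4 SD.
#' @param phase_dist Initial-phase law: `"uniform"` on (-pi, pi] (default) or
#'   `"von_mises_mixture"` with `phase_dist_pars`.
#' @param phase_dist_pars For the mixture: list with vectors `mu`, `kappa`,
#'   `w` (component means, concentrations, weights).
#' @param antiphase_exclusion Half-width, rad, of the excluded band around
#'   antiphase for the initial wrapped difference (default 0.15; must be < pi).
#' @param mix_fraction Proportion of A cells in the mixed ensemble (default
#'   0.5, the 1:1 mix).
#' @param n_rois ROIs per ensemble (default 5).
#' @param roi_jitter_kappa Von Mises concentration of the per-ROI phase jitter
#'   (default 50, i.e. jitter SD ~ 0.14 rad, the high-synchrony regime).
#' @param noise_sd Additive Gaussian reporter noise, intensity units (default
#'   0.1 = 10% of the unit oscillation amplitude).
#' @param amp_tau Amplitude-decay timescale, min (default 1000; mild
#'   photobleaching-like decay).
#' @param baseline_drift Amplitude of the slow additive baseline trend
#'   (default 0.1).
#' @param sampling_dt Reporter sampling interval, min (default 10, typical
#'   live-imaging cadence); must be a multiple of the integration step.
#' @param seed Integer seed (default 1).
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_triplets = 32L, period_mean = 137.5,
                          period_sd = 1.5, phase_dist = c("uniform",
                                                          "von_mises_mixture"),
                          phase_dist_pars = NULL, antiphase_exclusion = 0.15,
                          mix_fraction = 0.5, n_rois = 5L,
                          roi_jitter_kappa = 50, noise_sd = 0.1,
                          amp_tau = 1000, baseline_drift = 0.1,
                          sampling_dt = 10, seed = 1L) {
  phase_dist <- match.arg(phase_dist)
  if (n_triplets < 1L) stop("`n_triplets` must be >= 1", call. = FALSE)
  if (period_sd < 0) stop("`period_sd` must be >= 0", call. = FALSE)
  if (period_mean <= 0) stop("`period_mean` must be > 0", call. = FALSE)
  if (antiphase_exclusion < 0 || antiphase_exclusion >= pi) {
    stop("`antiphase_exclusion` must be in [0, pi)", call. = FALSE)
  }
  if (mix_fraction < 0 || mix_fraction > 1) {
    stop("`mix_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (n_rois < 1L) stop("`n_rois` must be >= 1", call. = FALSE)
  for (nm in c("roi_jitter_kappa", "noise_sd", "amp_tau", "baseline_drift",
               "sampling_dt")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0) {
      stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
    }
  }
  if (phase_dist == "von_mises_mixture") {
    p <- phase_dist_pars
    if (is.null(p) || !all(c("mu", "kappa", "w") %in% names(p))) {
      stop("von_mises_mixture needs phase_dist_pars$mu/kappa/w",
           call. = FALSE)
    }
  }
  structure(list(n_triplets = as.integer(n_triplets),
                 period_mean = period_mean, period_sd = period_sd,
                 phase_dist = phase_dist, phase_dist_pars = phase_dist_pars,
                 antiphase_exclusion = antiphase_exclusion,
                 mix_fraction = mix_fraction, n_rois = as.integer(n_rois),
                 roi_jitter_kappa = roi_jitter_kappa, noise_sd = noise_sd,
                 amp_tau = amp_tau, baseline_drift = baseline_drift,
                 sampling_dt = sampling_dt, seed = as.integer(seed)),
            class = "cohort_params")
}

# Von Mises sampler, Best & Fisher (1979) rejection scheme.
rvon_mises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3L)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    f <- max(-1, min(1, f))  # float guard at extreme concentrations
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2L] > 0 || log(cc / u[2L]) + 1 - cc >= 0) {
      out[i] <- wrap_phase(sign(u[3L] - 0.5) * acos(f) + mu)
      i <- i + 1L
    }
  }
  out
}

draw_initial_phase <- function(n, params) {
  if (params$phase_dist == "uniform") {
    stats::runif(n, -pi, pi)
  } else {
    p <- params$phase_dist_pars
    comp <- sample.int(length(p$w), n, replace = TRUE, prob = p$w)
    vapply(comp, function(k) rvon_mises(1L, p$mu[k], p$kappa[k]),
           numeric(1L))
  }
}

draw_period <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    x <- stats::rnorm(1L, mean, sd)
    if (abs(x - mean) <= 4 * sd && x > 0) {
      out[i] <- x
      i <- i + 1L
    }
  }
  out
}

#' Sample the latent parameters of a synthetic cohort
#'
#' Draws, for each triplet, the intrinsic frequencies of the two embryos
#' (omega = 2*pi/period, periods Normal(period_mean, period_sd) truncated at
#' +/- 4 SD) and the two initial phases, redrawing any pair whose wrapped
#' difference falls within `antiphase_exclusion` of antiphase (where "ahead"
#' is experimentally ambiguous). Sets the RNG from `params$seed`, so the same
#' parameters always yield the same cohort.
#'
#' @param params A [cohort_params()].
#' @return Data frame with one row per triplet: `triplet`, `period_a`,
#'   `period_b`, `omega_a`, `omega_b`, `phi_a0`, `phi_b0`.
#' @export
sample_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n_triplets
  period_a <- draw_period(n, params$period_mean, params$period_sd)
  period_b <- draw_period(n, params$period_mean, params$period_sd)
  phi_a0 <- phi_b0 <- numeric(n)
  lim <- pi - params$antiphase_exclusion
  for (i in seq_len(n)) {
    repeat {
      pa <- draw_initial_phase(1L, params)
      pb <- draw_initial_phase(1L, params)
      if (abs(wrap_phase(pa - pb)) <= lim) break
    }
    phi_a0[i] <- pa
    phi_b0[i] <- pb
  }
  data.frame(triplet = seq_len(n), period_a = period_a, period_b = period_b,
             omega_a = 2 * pi / period_a, omega_b = 2 * pi / period_b,
             phi_a0 = phi_a0, phi_b0 = phi_b0)
}

#' Synthesize reporter traces for one triplet
#'
#' Evolves the two reference ensembles uncoupled at their intrinsic
#' frequencies and the mixed ensemble's two subpopulation phases under the
#' given coupling model (weighted by `mix_fraction`), then emits `n_rois`
#' reporter-like intensity traces per ensemble:
#' `value(t) = baseline(t) + exp(-t/amp_tau) * cos(phase(t) + roi_jitter)
#' + noise`, with the mixed trace mixing the two subpopulation cosines in
#' proportion to `mix_fraction`. Phase zero is the reporter peak (cosine
#' convention). Consumes the current RNG stream; seed at the cohort level
#' (see [generate_cohort()]).
#'
#' @param latent One-row data frame from [sample_cohort()].
#' @param model A [coupling_model()].
#' @param cfg A [sim_config()].
#' @param params A [cohort_params()].
#' @return List with `signals` (tidy data frame: `time_min`, `ensemble_id`,
#'   `roi_id`, `intensity`), `truth` (data frame: `time_min`, `ensemble_id`,
#'   `oscillator`, `phase_rad`) and `latent`.
#' @export
synthesize_triplet <- function(latent, model, cfg = sim_config(),
                               params = cohort_params()) {
  stopifnot(is.data.frame(latent), nrow(latent) == 1L)
  step <- params$sampling_dt / cfg$dt
  if (abs(step - round(step)) > 1e-8) {
    stop("`sampling_dt` must be a multiple of the integration step",
         call. = FALSE)
  }
  sub <- seq(1L, floor(cfg$t_end / cfg$dt + 1e-9) + 1L, by = round(step))
  a <- oscillator_spec(latent$omega_a, latent$phi_a0, "A")
  b <- oscillator_spec(latent$omega_b, latent$phi_b0, "B")
  mix <- simulate_mixture(a, b, model, params$mix_fraction, cfg)
  times <- mix$a$times[sub]
  ph <- list(
    A = latent$phi_a0 + latent$omega_a * times,
    B = latent$phi_b0 + latent$omega_b * times,
    AB_A = mix$a$phases[sub],
    AB_B = mix$b$phases[sub]
  )
  if (cfg$noise_sd > 0) {  # phase diffusion also applies to the references
    ref <- simulate_ensemble(
      list(a, b), coupling_model("kuramoto", c = 0), cfg)
    ph$A <- ref[[1L]]$phases[sub]
    ph$B <- ref[[2L]]$phases[sub]
  }
  p <- params$mix_fraction
  env <- exp(-times / params$amp_tau)
  make_rois <- function(osc_fun, ensemble_id) {
    do.call(rbind, lapply(seq_len(params$n_rois), function(r) {
      jit <- rvon_mises(1L, 0, params$roi_jitter_kappa)
      drift_phase <- stats::runif(1L, 0, 2 * pi)
      base <- 2 + params$baseline_drift *
        sin(2 * pi * times / 2000 + drift_phase)
      val <- base + env * osc_fun(jit) +
        stats::rnorm(length(times), 0, params$noise_sd)
      data.frame(time_min = times, ensemble_id = ensemble_id,
                 roi_id = r, intensity = val)
    }))
  }
  signals <- rbind(
    make_rois(function(j) cos(ph$A + j), "A"),
    make_rois(function(j) cos(ph$B + j), "B"),
    make_rois(function(j) p * cos(ph$AB_A + j) + (1 - p) * cos(ph$AB_B + j),
              "AB")
  )
  truth <- rbind(
    data.frame(time_min = times, ensemble_id = "A", oscillator = "A",
               phase_rad = ph$A),
    data.frame(time_min = times, ensemble_id = "B", oscillator = "B",
               phase_rad = ph$B),
    data.frame(time_min = times, ensemble_id = "AB", oscillator = "A",
               phase_rad = ph$AB_A),
    data.frame(time_min = times, ensemble_id = "AB", oscillator = "B",
               phase_rad = ph$AB_B)
  )
  list(signals = signals, truth = truth, latent = latent)
}

#' Generate a full synthetic cohort
#'
#' [sample_cohort()] (which seeds the RNG from `params$seed`) followed by
#' [synthesize_triplet()] for every triplet on the one resulting RNG stream;
#' regeneration from the same parameters is bit-identical.
#'
#' @inheritParams synthesize_triplet
#' @return List with `signals` and `truth` (tidy data frames carrying a
#'   `triplet` column), `latent` (the cohort table) and `params`.
#' @export
generate_cohort <- function(params = cohort_params(),
                            model = coupling_model("reku_plus"),
                            cfg = sim_config()) {
  latent <- sample_cohort(params)
  trips <- lapply(seq_len(nrow(latent)), function(i) {
    synthesize_triplet(latent[i, , drop = FALSE], model, cfg, params)
  })
  signals <- do.call(rbind, lapply(seq_along(trips), function(i) {
    cbind(triplet = i, trips[[i]]$signals)
  }))
  truth <- do.call(rbind, lapply(seq_along(trips), function(i) {
    cbind(triplet = i, trips[[i]]$truth)
  }))
  rownames(signals) <- rownames(truth) <- NULL
  list(signals = signals, truth = truth, latent = latent, params = params)
}

#' Write a synthetic cohort to disk
#'
#' Tidy CSVs (`signals.csv`, `truth.csv`, `latent.csv`) plus a JSON sidecar
#' (`params.json`) holding the full generator parameters, so the cohort can be
#' either reloaded or regenerated bit-identically from the seed.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$signals, file.path(dir, "signals.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$latent, file.path(dir, "latent.csv"),
                   row.names = FALSE)
  p <- cohort$params
  p$phase_dist_pars <- p$phase_dist_pars %||% NULL
  jsonlite::write_json(unclass(p), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a synthetic cohort from disk
#'
#' Inverse of [write_cohort()]. Row order in the CSVs is immaterial (rows are
#' re-sorted on their keys); missing required columns and ragged or
#' non-uniform time grids raise errors rather than being silently repaired.
#'
#' @param dir Directory written by [write_cohort()].
#' @return List with `signals`, `truth`, `latent`, `params` as in
#'   [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  need <- function(df, cols, file) {
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      stop(sprintf("%s is missing required column(s): %s", file,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  signals <- utils::read.csv(file.path(dir, "signals.csv"))
  need(signals, c("triplet", "time_min", "ensemble_id", "roi_id",
                  "intensity"), "signals.csv")
  signals <- signals[order(signals$triplet, signals$ensemble_id,
                           signals$roi_id, signals$time_min), ,
                     drop = FALSE]
  rownames(signals) <- NULL
  key <- interaction(signals$triplet, signals$ensemble_id, signals$roi_id,
                     drop = TRUE)
  lens <- tapply(signals$time_min, key, length)
  if (length(unique(lens)) != 1L) {
    stop("ragged series: ROIs have unequal numbers of samples",
         call. = FALSE)
  }
  for (k in levels(key)) {
    check_uniform_times(signals$time_min[key == k],
                        sprintf("time grid of series %s", k))
  }
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  need(truth, c("triplet", "time_min", "ensemble_id", "oscillator",
                "phase_rad"), "truth.csv")
  truth <- truth[order(truth$triplet, truth$ensemble_id, truth$oscillator,
                       truth$time_min), , drop = FALSE]
  rownames(truth) <- NULL
  latent <- utils::read.csv(file.path(dir, "latent.csv"))
  pj <- jsonlite::read_json(file.path(dir, "params.json"),
                            simplifyVector = TRUE)
  params <- cohort_params(
    n_triplets = pj$n_triplets, period_mean = pj$period_mean,
    period_sd = pj$period_sd, phase_dist = pj$phase_dist,
    phase_dist_pars = pj$phase_dist_pars,
    antiphase_exclusion = pj$antiphase_exclusion,
    mix_fraction = pj$mix_fraction, n_rois = pj$n_rois,
    roi_jitter_kappa = pj$roi_jitter_kappa, noise_sd = pj$noise_sd,
    amp_tau = pj$amp_tau, baseline_drift = pj$baseline_drift,
    sampling_dt = pj$sampling_dt, seed = pj$seed)
  list(signals = signals, truth = truth, latent = latent, params = params)
}
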