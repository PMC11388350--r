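---
title: "Models and methods: nonreciprocal synchronization of oscillator ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: nonreciprocal synchronization of oscillator ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rekusync)
```

## The phase description and its assumptions

Each cell ensemble is reduced to a single phase variable $\varphi(t)$
advancing at an intrinsic angular frequency $\omega$ (defaults emulate the
mouse segmentation clock: $\omega = 0.0457$ rad/min, a 137.5-min period).
This coarse-graining assumes (i) each plated ensemble is internally
synchronized — justified empirically by near-unit Kuramoto order parameters
across regions of interest — and (ii) the mixed ensemble is well mixed, so
interactions depend only on the two subpopulation phases, not on space.
Amplitude dynamics are ignored; the reporter enters only through the
observation model of the synthetic generator.

Coupled pairs follow
$$\dot\varphi_A = \omega_A + c\,H(\varphi_B - \varphi_A), \qquad
  \dot\varphi_B = \omega_B + c\,H(\varphi_A - \varphi_B),$$
with the phase difference always wrapped to $(-\pi, \pi]$ (boundary kept at
$+\pi$) before $H$ is evaluated, which enforces $2\pi$-periodicity exactly.
The averaged description is valid when the coupling is weak relative to the
oscillation ($c \ll \omega$); `simulate_pair_pulsed()` integrates the
unaveraged signal/response product $c\,R(\varphi_{\rm self})
S(\varphi_{\rm other})$ for the regimes where averaging fails.

## Coupling families

`coupling_model()` implements:

* **Kuramoto** $H = \sin\Delta\varphi$ — reciprocal, predicts phase
  averaging.
* **Kuramoto–Sakaguchi** $H = \sin(\Delta\varphi + \alpha) - \sin\alpha$ —
  frustrated but lacking the second asymmetry; the subtraction keeps
  $H(0) = 0$ so in-phase ensembles stay put.
* **Rectified (ReKu)** $H^+ = \max(0, \sin\Delta\varphi)$ and
  $H^- = \min(0, \sin\Delta\varphi)$ — zero on one half-cycle and
  single-signed on the other (the "double asymmetry" behind
  winner-takes-it-all).
* **Continuous ReKu** interpolating between these with an asymmetry
  parameter $\beta$.
* **custom_rs** — an explicit $(R, S)$ pair, used directly by the pulsed
  integrator or cycle-averaged by `effective_coupling()`.

### The continuous-ReKu sign convention

Two conventions are provided. The default, `ahead_wins_negative_beta`,
evaluates $H = \sin(\Delta\varphi)\,(1 - \tanh(\beta\,\Delta\varphi))$, so
$\beta \to -\infty$ gives $2H^+$ (ahead wins), $\beta = 0$ is Kuramoto, and
$\beta \to +\infty$ gives $2H^-$. The alternative `literal_eq9` evaluates
$\sin(\Delta\varphi)(1 + \tanh(\beta\,\Delta\varphi))$, which mirrors the
$\beta$ limits. With the $\Delta\varphi = \varphi_{\rm other} -
\varphi_{\rm self}$ argument convention used throughout this package, only
the default form makes strongly negative $\beta$ produce ahead-wins
dynamics, so the default is anchored to that behavioral requirement; the
mirrored form is retained behind the flag for comparison. The factor 2 in
the saturated limits is deliberate and absorbed into the coupling strength
$c$ rather than renormalized away. Numerically, the saturated limits at
$\beta = \mp 50$ agree with $2H^\pm$ to better than $10^{-6}$ once
$|\Delta\varphi| \gtrsim 0.15$; closer to zero the $\tanh$ gap
$|\sin\Delta\varphi|(1 - \tanh(50|\Delta\varphi|))$ is itself of order
$10^{-5}$, an intrinsic property of the formula.

### Effective coupling by cycle averaging

`effective_coupling()` computes
$H(\Delta\varphi) = \frac{1}{2\pi}\int_0^{2\pi} R(u)\,S(\Delta\varphi+u)\,du$
by the trapezoid rule on a uniform periodic grid (default 512 points), which
is spectrally accurate for smooth periodic integrands; the closed forms
$R \equiv 1, S = \sin \Rightarrow H \equiv 0$ and
$R = S = \sin \Rightarrow H = \cos(\Delta\varphi)/2$ are reproduced to
$10^{-12}$. As the signal pulse narrows, $H(\Delta\varphi) \to
R(-\Delta\varphi)\cdot\text{mass}/2\pi$: a pulse-like sender simply reads
out the mirrored response curve, which is how a doubly asymmetric $R$
produces a ReKu-like coupling function.

### Pulsed-coupling stand-ins

The exact pulse and response shapes of the strong-coupling experiment are
not fixed by theory, so the package parameterizes them:
`pulse_signal_fn(kappa = 200)` is a von Mises-shaped pulse at the reporter
peak (width $\approx 1/\sqrt{\kappa} \approx 0.07$ rad, i.e. the sender is
"on" for a few minutes of a 137-min cycle), and two response shapes are
provided. `sinusoidal_response_fn()` ($R = -\sin\varphi$) is the
model-comparison default: its cycle average is Kuramoto-like, and in the
strong-coupling regime ($c \sim 10\omega$) each pulse resets the partner
toward the sender's phase, which yields winner-takes-it-all only for small
phase differences and diverges near antiphase — the falsifiable behavior a
non-rectified pulsed model should show. `asymmetric_response_fn()`
($R = \max(0, -\sin\varphi)$) is the doubly asymmetric alternative whose
pulsed dynamics remain winner-takes-it-all at essentially all phase
differences; it demonstrates how pulsatile senders plus a rectified response
reproduce ReKu-like synchronization. A wide pulse (small $\kappa$) lets the
pulse tail overlap the response's active region and perturbs the putative
winner; $\kappa = 200$ keeps that leakage negligible.

## Integration

Deterministic trajectories use fixed-step classical RK4 (default
$dt = 0.1$ min, rejected if $dt \ge$ period/20); with 137-min periods this
is inexpensive, reproducible, and converged — halving $dt$ moves final
phases by $< 10^{-7}$ rad, and an independent adaptive solver (deSolve's
`ode45`) agrees to $10^{-6}$. Phase noise, when requested, switches to
Euler–Maruyama with independent increments per oscillator
(`noise_sd` in rad/$\sqrt{\text{min}}$, one stream per seed). The
synthetic-cohort frequency dispersion is modeled as per-ensemble period
draws rather than integration noise, matching how slice-to-slice variability
enters the experiment; phase diffusion remains available as an option.

The delayed pair $\dot\varphi_A(t) = \omega_A + c\sin(\varphi_B(t-\tau) -
\varphi_A(t))$ uses a constant pre-history $\varphi(t<0) = \varphi_0$
(oscillators run uncoupled before mixing) and a linearly interpolated
history buffer inside each RK4 stage; when a stage needs a value newer than
the buffer head (only possible for $\tau < dt$) it uses the partner's
current stage value, making $\tau = 0$ reduce *exactly* to the Kuramoto
pair. For small $c\tau$ the locked state matches a Kuramoto–Sakaguchi pair
with $\alpha = -\omega\tau$ to first order; only that first-order statement
is asserted (within 0.05 rad at $c = 0.005$, $\tau = 20$ min), since the
exact $\alpha(\tau, \Omega, c)$ correction involves the self-consistent
collective frequency.

Mean-field ensembles use all-to-all coupling normalized by the number of
partners, $\dot\varphi_i = \omega_i + \tfrac{c}{N-1}\sum_{j\ne i}
H(\varphi_j - \varphi_i)$, so $c$ retains the same meaning for pairs and
ensembles and $N = 2$ reduces identically to the pair equations. The
two-subpopulation mixture with an A-fraction $p$ uses weights $2c(1-p)$ and
$2cp$, normalized so $p = 1/2$ is exactly the pair.

## The synthetic cohort generator

`cohort_params()` fixes the study conditions: 32 triplets; periods
Normal(137.5, 1.5) min truncated at $\pm 4$ SD (the empirical spread is
narrow but not printed anywhere, so the scale is config-exposed); initial
phases uniform on $(-\pi, \pi]$ — the conservative choice given that the
empirical distribution spans the circle but is slightly narrower — with
redraws whenever the wrapped difference falls within 0.15 rad of antiphase,
where "ahead" is undefined; a 1:1 mix; 5 ROIs per ensemble with von Mises
phase jitter ($\kappa = 50$, jitter SD $\approx 0.14$ rad, reproducing the
observed near-unit order parameters). Each ROI trace is
$$\text{value}(t) = 2 + 0.1\sin(2\pi t/2000 + \psi)
 + e^{-t/1000}\cos(\varphi(t) + \text{jitter}) + \varepsilon,$$
with $\varepsilon \sim N(0, 0.1)$: phase zero is the reporter peak (cosine
convention), amplitude decays mildly (timescale 1000 min) and the baseline
drifts slowly at 10% of the oscillation amplitude — enough to exercise
detrending without drowning the signal. Mixed-ensemble traces superpose the
two subpopulation cosines weighted by the mix fraction. Reporter sampling is
every 10 min over 600 min, the live-imaging cadence. References share their
subpopulation's intrinsic frequency (a same-embryo split), which is what
makes "the winner matches its own reference" a clean readout.

What the generator does **not** emulate: cell movement, division or
delamination; spatial structure within an ensemble (ROIs differ only by
jitter and noise); amplitude-phase interaction; non-stationary periods
(the in-vivo slowing-down). Passing tests therefore demonstrate correctness
of the inference machinery under the stated observation model, not
robustness to every artifact of live imaging.

## Phase estimation

`estimate_phase()` offers two deliberately independent routes:

* **Wavelet ridge** — Morlet continuous wavelet transform (central
  frequency 6, the standard time-frequency trade-off) over 150 log-spaced
  periods in 60–300 min (bracketing the clock); per time point the ridge
  maximizes scale-normalized power, the phase is the argument of the ridge
  coefficient, and the period comes from the smoothed phase derivative with
  a parabolic-in-log-period fallback.
* **Analytic signal** — a Hamming-windowed FIR Hilbert transformer (half
  length about two mid-band periods) applied to the mirror-padded, detrended
  trace. Mirror padding plus the finite kernel keeps boundary leakage out of
  the interior, where a plain FFT Hilbert on a short segment leaves
  0.05–0.1 rad of ripple.

Both unwrap cumulatively (nearest branch) and flag one dominant period at
each end as `quality = 0`; low-quality samples are never extrapolated.
Detrending subtracts a centered moving average (reflected edges, exact
removal of constants). On clean 800-min traces both methods recover phase
to better than 0.05 rad and period to better than 2% away from the edges;
on default-noise synthetic cohorts the ensemble-level (circular mean over
5 ROIs) error at the 400-min readout has median $\approx$ 0.04–0.07 rad.
That error bound is what justifies the 0.3-rad classification tolerance
from below. Parity with any particular wavelet toolbox is not a goal; the
ground-truth recovery bounds are.

Synchrony uses the Kuramoto order parameter
$R = |n^{-1}\sum_j e^{i\varphi_j}|$ and the standard circular SD
$\sqrt{-2\ln R}$ (infinite for perfectly dispersed samples, zero exactly at
perfect synchrony; the implementation snaps $R > 1 - 10^{-15}$ to 1 so the
two degenerate ends are exact).

## Classification

`label_ahead()` calls A ahead when $\mathrm{wrap}(\varphi_A - \varphi_B) \in
(0, \pi)$, with an ambiguity band of 0.15 rad around antiphase (such
triplets are tracked but excluded from fraction denominators, mirroring how
near-antiphase experiments cannot be averaged). `classify_outcome()` places
each triplet at $x = \mathrm{wrap}(\varphi_{\rm behind} - \varphi_{\rm mix})$,
$y = \mathrm{wrap}(\varphi_{\rm ahead} - \varphi_{\rm mix})$ at the 400-min
readout and applies, in priority order: both-within-tolerance
(`degenerate_in_phase` — resolves the near-in-phase corner where
ahead/behind is meaningless), ahead axis, behind axis, averaging diagonal
($|x + y| \le$ tol), else `other`. The default tolerance of 0.3 rad is
config-exposed; it must exceed — and by the measured estimation error
comfortably does exceed — the ensemble-level phase error of the estimation
stack. The averaging test uses the literal sum $|x+y|$, so a mixture sitting
at the *far* circular midpoint is classed `other`, not `averaging`; the
diagonal of interest is the near midpoint.

## Problem sizes

The shipped analyses use 32-triplet cohorts for the headline counts (about
8 s of CPU via the phase-only path), 16-triplet cohorts for sweeps,
12-triplet full-signal cohorts for the estimation stack, and 16-oscillator
ensembles for the minority-ahead experiment — sizes chosen to match the
experimental cohort (n = 32) and to keep every analysis comfortably
desk-scale while leaving Monte-Carlo checks (e.g. 2×10⁴ order-parameter
replicates) statistically decisive.

## Known limitations

* The classifier consumes phases at a single readout time; it does not test
  for stable locking over an interval (the underlying models lock
  monotonically, so this is safe in simulation but would be worth
  strengthening for data with period drift).
* The delayed model asserts only the first-order $\alpha \approx
  -\omega\tau$ reduction.
* The pulsed-coupling shapes are parameterized stand-ins; conclusions about
  the pulsed regime are qualitative (which regimes can/cannot produce
  winner-takes-it-all), not quantitative fits.
* `fraction_ahead_wins` counts only unambiguous `ahead_wins` triplets;
  near-in-phase starts land in `degenerate_in_phase` and are winner-
  takes-it-all without contributing to the ahead-wins count.
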