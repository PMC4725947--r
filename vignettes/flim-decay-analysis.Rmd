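---
title: "Bi-exponential FLIM decay analysis: model, fitting and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-exponential FLIM decay analysis: model, fitting and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimetry)
```

## The measurement and the model

Time-correlated single photon counting (TCSPC) FLIM histograms the arrival
delay of each emitted photon relative to its excitation pulse, per pixel.
NADH and FAD autofluorescence decays are well described by a double
exponential,

$$ I(t) = a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2}, $$

whose components correspond to the free and protein-bound pools of the
coenzyme: for NADH the free form is the short-lived component
($\tau_1 \approx 0.4$ ns) and the bound form long-lived
($\tau_2 \approx 2.5$ ns); for FAD the assignment is reversed. The
amplitude ratios $a_1/a_2$ (NADH) and $a_2/a_1$ (FAD) therefore measure the
free-to-bound balance and act as optical redox metrics. The average
lifetime is reported in two conventions: amplitude-weighted,
$(a_1\tau_1 + a_2\tau_2)/(a_1+a_2)$, the package default because the
amplitudes are defined as fractional contributions, and intensity-weighted,
$(a_1\tau_1^2 + a_2\tau_2^2)/(a_1\tau_1 + a_2\tau_2)$. Both are always
computed; published FLIM work is divided on the convention and the two can
differ substantially (the intensity-weighted mean is not even monotone in
$\tau_1$: $\partial\tau_I/\partial\tau_1 =
a_1\tau_1^2 + a_2\tau_2(2\tau_1-\tau_2)$ is negative when
$\tau_2 > 2\tau_1$ and $a_1$ is small). Group-contrast conclusions in this
package are therefore drawn from $\tau_1$, $\tau_2$ and the amplitude
ratio, with $\tau_{avg}$ reported in both modes but never used as the
decisive statistic.

What the detector records is the decay convolved with the instrument
response function (IRF). At an 82 MHz repetition rate the period is
12.195 ns — only ~5 times $\tau_2$ — so fluorescence from earlier pulses
survives into the current window. `convolve_periodic()` handles this
*incomplete decay* exactly: each exponential is wrapped in closed form,
$\sum_{k\ge 0} e^{-(t+kT)/\tau} = e^{-t/\tau}/(1-e^{-T/\tau})$, and then
circularly convolved with the IRF profile over the period (via FFT; a
brute-force $O(n^2)$ sum is the test oracle, agreement to $10^{-10}$).
Two nuisance parameters complete the model: a constant detector dark-count
background per bin, and a temporal shift between IRF and decay (from the
wavelength dependence of the detection chain), applied to the IRF with
sub-bin linear interpolation so it can be optimised continuously.

## Defaults and units

| parameter | default | unit | rationale |
|---|---|---|---|
| time axis | 256 bins × 47.6 ps | — | resolves τ ≥ 0.15 ns against a 0.181 ns IRF; window fills one 12.195 ns period (82 MHz) |
| IRF | Gaussian, FWHM 0.181 ns, centre 0.6 ns | ns | typical urea-film SHG calibration width; a measured profile can replace it via `irf_model()`/`read_irf_csv()` |
| lifetime bounds | [0.01, 10] | ns | generous physical range for NADH/FAD |
| shift bound | ±1 | ns | much larger than any realistic detection-chain offset |
| photon floor | 1000 | counts | minimum for a stable bi-exponential fit; pixels are adaptively binned up to 15×15 until they reach it |
| convergence | ftol = ptol = 1e-8, ≤ 400 iterations | — | deterministic, tight relative tolerances |

## Fitting

`fit_decay()` minimises the Poisson-weighted ("Neyman") sum of squares
$\sum_b (y_b - \mu_b)^2/\max(y_b, 1)$ over $(a_1, \tau_1, a_2, \tau_2,
\mathrm{bg}, \mathrm{shift})$ with bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`). Weighting by the observed counts is the
conventional reading of "least squares assuming Poisson noise";
$\max(\cdot,1)$ guards empty bins. All bins participate in the objective —
with a periodic model, the pre-rise bins carry real information about the
background and the wrapped tail — while bins with zero counts are excluded
from the reduced chi-square.

Numerical choices worth recording:

* **Initialisation.** Background from the mean of the dimmest 5% of bins
  (the pre-rise region, located robustly rather than by position, since the
  rising edge can sit anywhere relative to the histogram start); $\tau_2$
  from a log-linear regression on the last 40% of the post-peak bins — with
  no floor subtraction, because a wrapped exponential is *exactly*
  exponential across the window and subtracting the floor would curve a
  straight log-tail; $\tau_1 = \tau_2/5$; amplitudes split to match the
  peak; shift 0.
* **Multi-start.** The wrap-around floor means the starting background can
  be badly overestimated, and a single start occasionally converges to a
  local minimum with the shift pinned at its bound. When the first
  solution's deviance per degree of freedom is poor, the optimiser retries
  from a small fixed set of alternative starts (background-free, canonical
  NADH-like, perturbed) and keeps the lowest deviance. All starts are
  deterministic, so fits remain pure functions of their inputs.
* **Canonical ordering.** Results always satisfy $\tau_1 \le \tau_2$;
  amplitudes swap with their lifetimes.
* **Identifiability.** When the fitted lifetimes end up within a factor of
  1.5 the result is flagged `poorly_separated` (the bi-exponential becomes
  ill-conditioned there) but ratio metrics are still reported.
* **Degenerate inputs.** An all-zero histogram is an error; a
  pure-background histogram yields a non-converged flag or amplitudes at
  the noise floor, never a silently plausible-looking result.

Goodness of fit: reduced chi-square over the non-empty bins (calibrated to
mean ≈ 1 on correctly specified Poisson simulations) and a two-sided
Wald–Wolfowitz runs test on the residual signs (structured residuals give
small p).

## Images, binning and ROIs

`adaptive_bin()` grows a centred square neighbourhood (1, 3, 5, … up to
15×15, clipped at image borders — no fabricated counts) around each pixel
until its summed histogram reaches the photon floor; pixels that never
reach it are invalid. `fit_image()` then fits every masked, valid pixel and
returns per-pixel maps of $\tau_1$, $\tau_2$, both $\tau_{avg}$ modes, the
amplitude ratio, chi-square, photon totals and kernel sizes.
`roi_mean_params()` averages valid pixels per ROI label **unweighted**, as
a plain mean over cytoplasmic pixels; ROI masks are supplied (drawn
manually in practice; synthetic phantoms generate their own) and exclude
nuclei. On homogeneous synthetic ROIs, averaging pixel-wise fits and
fitting the pooled ROI histogram agree on $\tau_{avg}$ to within 10%,
mirroring the empirical robustness of pixel-averaged lifetime estimates.
Pseudocolour maps use a fixed palette clipped to a common range so images
are directly comparable; invalid pixels render black.

## The synthetic-data generator

Because raw acquisitions of this kind are rarely released, validation rests
on a generator that emulates the study conditions rather than on deposited
data:

* **Presets** (`default_presets()`): control values use canonical
  literature lifetimes — NADH 0.40/2.50 ns with $a_1/a_2 = 2.0$, FAD
  0.45/2.80 ns with $a_2/a_1 = 1.5$. The 1000 µM MPP⁺ group applies the
  full treatment effect (NADH: τ1 −17%, τ2 −11%, ratio +60%; FAD: τ1 −32%,
  τ2 −10%, ratio −27%). Only these *percent deltas* are treated as pinned;
  the absolute control values are a documented choice, and all recovery
  targets are percent changes precisely so they are insensitive to it.
* **Plateau rule**: the NADH 50/100/250 µM doses share one preset (30% of
  the full effect — a value chosen once to sit clearly between control and
  the 500 µM group) and 500 µM carries 60%, reproducing the reported
  significance pattern (no separation within 50–250, separation of 500 vs
  1000); all treated FAD doses share the full-effect preset (treated FAD
  groups are statistically indistinguishable).
* **Biological scatter**: lognormal, cv = 0.05 per parameter per ROI, plus
  a day effect of cv = 0.02 shared within a day — magnitudes that give SEMs
  at n = 75 comparable to published FLIM dose studies, making p < 0.001
  attainable without being trivial.
* **Design**: 6 concentrations × 5 days × 15 ROIs = 75 rows per condition;
  one pooled histogram of 5·10⁵ photons per ROI (pooling keeps the
  450-fit experiment at desk scale; full per-pixel stacks are exercised by
  the imaging tests instead). Phantoms are seeded elliptical cells with
  interior nuclei and speckled cytoplasm; nuclei and background emit ≤ 5%
  of the cytoplasmic rate.

Every generator is a pure function of its seed. What the generator does
*not* emulate: photobleaching, detector afterpulsing and dead time,
spatial heterogeneity of the decay within a cell, segmentation error, and
any departure of real decays from the bi-exponential form. Passing
recovery tests therefore demonstrates that the estimation pipeline is
unbiased and well calibrated *under the stated model*, not that the model
is complete for real tissue.

## Statistics

`one_way_anova()` is the standard between/within decomposition (via
`stats::lm`); `lsd_posthoc()` implements Fisher's least significant
difference: unadjusted pairwise t-tests pooling the ANOVA within-group
variance, $t = (m_i - m_j)/\sqrt{MS_W(1/n_i + 1/n_j)}$ on $N-k$ degrees of
freedom — no multiplicity correction, which is the definition of the
procedure. Tests are two-sided. Rows are treated as independent
observations (matching the n = 75 analysis convention); the day column is
retained so a mixed-model extension remains possible, but none is fitted.
Significance tiers follow the figure-legend convention: `*` p < 0.05,
`**` p < 0.001. Zero within-group variance with unequal means returns p = 0
with a `degenerate` flag rather than NaN.

## Problem sizes used in validation

The shipped test suite runs the full 450-ROI experiment once per channel
(5·10⁵ photons per ROI), 100-replicate Monte-Carlo recovery at 10⁵ and 10⁶
photons, 200–500-replicate chi-square calibrations, and 1000-run type-I
calibrations for the ANOVA and runs test — sizes chosen so the whole suite
completes in about a minute while keeping Monte-Carlo standard errors well
below the asserted tolerances.

## Known limitations

* Bi-exponential only — no triple/stretched exponentials, no
  phasor-domain analysis, no anisotropy.
* Neyman weighting is slightly biased at very low counts; a Poisson
  deviance (MLE) estimator would fit behind the same `fit_decay()`
  interface but is not implemented.
* No global (multi-pixel) fitting; each pixel/ROI is independent.
* No vendor raw formats (PTU/TTTR/SPC); stacks enter as multi-page TIFF +
  JSON sidecar.
* ROI segmentation is out of scope; masks are inputs.
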