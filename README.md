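# flimetry

Quantification of cellular metabolic state from two-photon FLIM-TCSPC
measurements of the autofluorescent coenzymes NADH and FAD, for
microscopists and image analysts studying cellular energetics (e.g.
MPP⁺-induced Parkinsonian cell models, hypoxia, tumour metabolism).

## The model

A TCSPC histogram records photon arrival delays relative to the excitation
pulse. The fluorescence decay is modelled as a double exponential

    I(t) = a1 · exp(−t/τ1) + a2 · exp(−t/τ2)

where, for NADH, τ1 is the short lifetime of the free coenzyme and τ2 the
long lifetime of the protein-bound form, with fractional amplitudes a1, a2
(for FAD the assignment is reversed: short = bound, long = free). The
expected histogram is this decay convolved with the instrument response
function (IRF) — periodically, over the excitation period (12.195 ns at
82 MHz), so that fluorescence surviving from previous pulses ("incomplete
decay") wraps correctly into the window — plus a constant detector
background and a sub-bin temporal shift between IRF and decay.

Parameters are recovered by bounded Levenberg–Marquardt least squares with
Poisson (Neyman) weights 1/max(counts, 1); goodness of fit is judged by the
reduced chi-square (≈ 1 for a correct model) and a runs test on residual
signs. The amplitude ratios a1/a2 (NADH) and a2/a1 (FAD) are free-to-bound
redox metrics; the average lifetime is reported amplitude-weighted,
(a1τ1 + a2τ2)/(a1 + a2), and intensity-weighted.

Image stacks are processed pixel-by-pixel after adaptive square binning
that grows each pixel's neighbourhood until it holds ≥ 1000 photons; ROI
(cytoplasm, nuclei excluded) means feed a one-way ANOVA with Fisher's LSD
post-hoc comparison across treatment groups.

## Worked example

Simulate one NADH-like ROI histogram (5·10⁵ photons) and fit it:

```r
library(flimetry)
ax  <- time_axis()                      # 256 bins x 47.6 ps, 82 MHz period
irf <- gaussian_irf(ax)                 # 0.181 ns FWHM
truth <- decay_params(a1 = 2/3, tau1 = 0.40, a2 = 1/3, tau2 = 2.50,
                      background = 2)
h   <- simulate_histogram(truth, 5e5, ax, irf, seed = 1)
fit <- fit_decay(h, irf)
summary(fit)
```

```
Bi-exponential TCSPC decay fit summary

Coefficients:
         a1        tau1          a2        tau2  background       shift 
14542.09114     0.38873  7318.54546     2.47459     4.58078     0.00135 

free/bound amplitude ratio a1/a2: 1.987
tau_avg: 1.087 ns (amplitude-weighted), 1.978 ns (intensity-weighted)
chi2_red 0.961 | runs-test p 0.805 | converged | 500551 photons
```

The fitted lifetimes (0.389 / 2.475 ns) and ratio (1.99) recover the truth
(0.40 / 2.50 ns, 2.0) to a few percent at this photon budget; chi²ᵣ ≈ 1 and
a non-significant runs test say the model describes the data.

A full dose-group experiment (6 MPP⁺ concentrations × 5 days × 15 ROIs,
fitted per ROI) with its statistics:

```r
tab <- simulate_experiment(channel = "NADH", seed = 1)   # 450 fitted ROIs
analyze_experiment(tab, parameters = c("tau1", "tau2", "ratio"))
```

```
Dose-group analysis (control 0 vs 1000):
 parameter percent_change p_control_vs_treated
      tau1      -16.01112         3.170204e-66
      tau2      -10.94176         9.610955e-32
     ratio       59.82492        6.666273e-203
```

i.e. from control to 1000 µM the short and long NADH lifetimes drop by
~16% and ~11% while the free-to-bound ratio rises by ~60%, all far beyond
the p < 0.001 significance tier.

## Command line

A thin CLI over the same functions lives at `inst/cli/flimetry.R`
(subcommands `simulate`, `fit`, `map`, `analyze`, `report`); see
`?flim_cli`.
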