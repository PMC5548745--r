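---
title: "Quantifying membrane receptor dimerization from two-color fluctuation and photobleaching data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane receptor dimerization from two-color fluctuation and photobleaching data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerscope)
```

# The measurement problem

A cell-surface receptor tagged in two colors — say a GFP fusion and an
mCherry fusion co-expressed in the same cell — reports on its own
oligomerization through co-diffusion: if two protomers travel as one
complex, fluctuations of the green and red fluorescence collected from a
diffraction-limited spot on the plasma membrane are correlated. dimerscope
implements the quantitative chain that turns such recordings into dimer
statistics:

1. **Correlation estimation** from two-channel photon-count traces
   (multiple-tau algorithm, segment screening).
2. **Global model fitting** of the three correlation curves (green and red
   autocorrelation, cross-correlation) with a two-dimensional diffusion
   model including spectral crosstalk, channel backgrounds and imperfect
   focal overlap, in the two-step control/measurement procedure.
3. **Combinatorial dimer statistics**: the random-pairing model that
   predicts how many mixed-color dimers a fully dimerized population
   should show, and RMS agreement between measurement and model.
4. **Dynamic (time-lapse) series**: amplitude-ratio bound fractions,
   crosstalk correction and the normalizations used to display transient
   dissociation and re-association after agonist stimulation.
5. **Dual-color FRAP**: double normalization, window-based mobile
   fractions, crosslinking/stoichiometry screens and two-phase recovery
   fits.
6. A **synthetic-data generator** (Brownian dynamics plus Poisson photon
   emission, and a FRAP record generator) that produces data with exactly
   the statistical structure the analyses assume, so every estimator in
   the package can be validated against known ground truth.

# The correlation model

For species g (green-labeled), r (red-labeled) and gr (dual-labeled
complex) with surface concentrations $c_g, c_r, c_{gr}$ diffusing in 2D,
the model evaluated by `model_correlations()` is

$$G_G(\tau)-1 = \frac{A_G\left(x_g^2 c_g \mathrm{Diff}^G_g +
  c_{gr}\mathrm{Diff}^G_{gr}\right)}{\left(A_G(x_g c_g + c_{gr}) +
  BG_G\right)^2}$$

with the red autocorrelation and the cross-correlation carrying the
analogous terms plus the crosstalk contributions weighted by $K$ and
$K^2$, the displacement factor

$$\mathrm{Displ}(\tau) = \exp\!\left(\frac{-2r_0^2}
  {\omega_G^2+\omega_R^2+8D_{gr}\tau}\right)$$

for the lateral offset $r_0$ between the two laser foci, and 2D diffusion
factors $\mathrm{Diff}_u(\tau) = (1+4D_u\tau/\omega^2)^{-1}$.  The
effective detection areas are $A_G=\pi\omega_G^2$, $A_R=\pi\omega_R^2$,
$A_{GR}=\pi(\omega_G^2+\omega_R^2)/2$; the autocorrelation amplitude of a
single species is $1/(A\,c)$, the inverse of the mean number of molecules
in the detection area.

Two transcription details are worth stating explicitly.  First, the red
autocorrelation denominator is the square of the total red-channel
intensity $(A_R(x_r c_r + c_{gr}) + BG_R + A_G K(x_g c_g + c_{gr}))^2$ —
dimensional consistency and the $1/(Ac)$ amplitude limit require the
square.  Second, backgrounds are carried in counts/s by `species_model()`
(the simulator's units) and converted inside `model_correlations()` to
the molecule-equivalent intensity units of the model via $2\,bg/q$: a
molecule of brightness $q$ at the focus center contributes $q/2$ counts/s
on average over the Gaussian detection area.

## Parameters that matter

| parameter | meaning | unit | default | why |
|---|---|---|---|---|
| $\omega_G,\omega_R$ | detection radii | nm | 222, 272 | calibration values for 488/543 nm excitation in aqueous solution |
| $r_0$ | focal displacement | nm | bounded 100–150 in fits | instrument property, known only to a range |
| $x_g,x_r$ | cross-section ratios | – | 1 | 2 when the single-color species is itself a double-labeled homodimer |
| $K$ | spectral crosstalk | – | fit on controls, then fixed to the median | green emission detected in the red channel |
| $D$ | diffusion coefficients | µm²/s | 0.25–0.4 | membrane receptors; transit times 30–50 ms through a 222-nm spot |
| $c$ | surface concentrations | µm⁻² | 10–100 | the physiological expression range of the assay |

The defaults for $D$ deserve a note: the dimerization assay itself never
needs absolute diffusion coefficients, and published instrument-level
theory curves do not state them.  We fix the simulator defaults at
$D = 0.4$ µm²/s for single receptors and $0.25$ µm²/s for complexes —
transit times of $\omega_G^2/4D \approx 31$ and $49$ ms, inside the
1–150 ms acceptance window used by the QC screen — and expose them as
arguments everywhere.

# The two-step fitting procedure

Step one (`fit_control()`) uses measurements of cells in which no
dual-labeled complex can exist.  With $c_{gr}\equiv 0$ and the detection
radii fixed to their calibration values, the free parameters are
$c_g, c_r, D_g, D_r$ and the crosstalk $K$.  Because a control
measurement cannot determine the cross-section ratios, the fit is run for
each $(x_g, x_r)$ combination, and the median $K$ across control cells is
taken per combination (`median_control_K()`).  $D_{gr}$ and $r_0$ do not
enter the model when $c_{gr}=0$ (the displacement factor multiplies only
the complex term), so they are held fixed during step one rather than
left floating as unidentifiable parameters.

Step two (`fit_dimerization()`) fits measurement cells with $K$ fixed to
the control median, $r_0$ restricted to 100–150 nm, equal cross-section
ratios, and free concentrations and diffusion coefficients.  The derived
dimer fraction is $c_{gr}/(c_g+c_r+c_{gr})$.

**Optimizer.** Both steps use bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) on log-transformed concentrations and diffusion
coefficients, with five deterministically jittered starts; the best
sum-of-squares wins.  The three curves enter the objective with equal
weight.  Per-lag inverse-variance weights (from the across-segment
standard deviations) are applied only when at least eight segments
contributed: with the typical three to six 10-s segments, the variance
estimates are so noisy that weighting systematically overweights the
long-lag tail and measurably degrades parameter recovery — we verified
this on synthetic all-dimer batches (median recovered dimer fraction
0.86 weighted vs 0.92 unweighted at 60 s per cell).

**Finite-segment baselines.** Estimating a correlation curve from a
finite segment of length $T$ and normalizing by the segment mean
depresses the curve by a nearly constant offset of order
$2G_0\tau_D\ln(T/\tau_D)/T$; left uncompensated, this biased recovered
transit times by about −16 %.  Two measures remove it: segmented
measurements are normalized by the *global* mean over all kept segments
(`fccs_curves(..., normalization = "global")`), which also removes a
Jensen-type positive bias of the small cross-correlation amplitude that
would otherwise masquerade as extra crosstalk; and both the
single-component fit and the global fit include small additive baseline
parameters, bounded at $\pm 5\times 10^{-3}$ — the physical magnitude of
the residual effect.  Wider offset bounds are harmful: they let the
cross-curve baseline absorb genuine co-diffusion amplitude.

**Quality control.** `apply_qc()` reproduces the inclusion screen:
total included time 20–80 s, transit time 1–150 ms, single-species fit
$R^2 \in [0.9, 1]$, molecular brightness 0.2–2.5 kHz per molecule in each
channel and a green/red brightness ratio of 0.5–2.5.  Segment screening
(`screen_segments()`) discards acquisition intervals containing intensity
spikes (aggregates) or monotone decays (membrane movement); the published
rejection rule is qualitative, so the thresholds (`spike_z = 8` within-
segment standard deviations, 30 % decay per segment) are module
parameters and make no claim to reproduce any manual curation.

# Dimer combinatorics

If $M$ green and $N$ red molecules pair at random, the probability that a
dimer is mixed is exactly $2MN/((M+N)(M+N-1))$
(`enumerate_pairings()`, verified by exhaustive enumeration of all
perfect pairings for $M+N \le 12$), and in the large-population
approximation

$$p_{gr}=\frac{(2c_{gg}+c_{gr})(2c_{rr}+c_{gr})}
  {2(c_{gg}+c_{gr}+c_{rr})^2},$$

the printed form used by `pair_probability()`; the two differ by at most
$1/(M+N)$.  The expected mixed-dimer concentration under random pairing
is $c'_{gr} = p_{gr}(c_{gg}+c_{gr}+c_{rr})$
(`expected_crossdimer()`); the ratio $c_{gr}/c'_{gr}$ equals 1 for any
binomially assembled population, which makes it the natural "percentage
of dimerization" axis.  The package reports both this ratio and the raw
mixed fraction, since either normalization is defensible.
`model_agreement_rms()` summarizes a batch of cells as the RMS deviation
between measured mixed-dimer fractions and the all-dimer (or zero-dimer)
prediction.

# Dynamic dissociation series

Time-lapse experiments are reduced with amplitude ratios rather than full
global fits: the fraction of red diffusing units also carrying green is
$N_{gr}/N_r = (G_{cc}(0)-1)/(G_g(0)-1)$ (`bound_fraction()`), with
amplitudes from one-component fits per time point.  These per-point fits
deliberately omit the additive baseline used elsewhere and cap lags at
1 s: with only 30–60 s of data per time point a free baseline trades
against the amplitude and inflates point-to-point variance, while the
(common) additive bias cancels in the pre-stimulation normalization —
on synthetic dip experiments the baseline-free estimator raised the
median rank correlation with the programmed schedule from 0.76 to 0.93.  Focal displacement is
deliberately ignored here — the series is interpreted relative to its
pre-stimulation value (`normalize_dynamic_series()`, reference = the
pre-stimulation point; normalizing to the first post-stimulation point
would be the alternative reading, and the reference index is an
argument).  Spurious cross-correlation from crosstalk is removed at the
amplitude level by `correct_crosstalk_amplitude()` using the
intensity-bleed model $I_r^{meas} = I_r^{true} + \kappa I_g$; the
defining property — green-only data correct to zero in expectation — is
what the tests enforce.  Cells with $I_g/I_r > 1$ are deselected
(`intensity_ratio_screen()`).

# Dual-color FRAP

`normalize_recovery()` performs standard double normalization
(background-subtracted bleach region over background-subtracted reference
region, scaled to the pre-bleach mean), which cancels whole-field
acquisition bleaching exactly.  The mobile fraction is
$F_m = (I_P - I_0)/(I_I - I_0)$ with $I_I$ the pre-bleach mean, $I_0$ the
*first post-bleach frame* (a single frame, not an average — the
immediately-post-bleach reading), and $I_P$ the mean inside the 85–101 s
assessment window on an experiment clock that includes the 15-s pre-bleach
span; window boundaries are arguments.  `fit_two_phase()` fits the
two-phase association model $I_0 + A[s(1-e^{-k_1t}) + (1-s)e^{-k_2t}
\ldots]$ with $k_1 \ge k_2$ enforced by construction and a degeneracy
flag when the two phases collapse.  An interaction experiment is included
only if crosslinking reduced the mobile fraction of the anchored
population by at least 40 % relative to its uncrosslinked baseline
(evaluated per ROI against the condition baseline; a per-experiment
aggregate is also reported by the analysis scripts) and the green/red
intensity ratio stays below 1.6 (`crosslink_screen()`).

# The synthetic-data generator

`simulate_membrane_traces()` places Poisson-distributed numbers of
particles of the three species uniformly on a periodic square membrane
patch and propagates them with Gaussian steps of standard deviation
$\sqrt{2D\,dt}$ per axis and sampling interval.  Expected per-bin counts
are sums of molecular brightness times the Gaussian detection profile
$\exp(-2r^2/\omega^2)$ (green focus at the patch center, red focus
displaced by $r_0$), green emission leaks into the red channel with
weight $K$, backgrounds add, and photon counts are Poisson.  Defaults:
$dt = 0.5$ ms (well below the shortest fitted lag of 1 ms; batch analyses
use 1 ms), patch 3×3 µm — ≥ 13 detection radii, large enough that
periodic images are uncorrelated with the focus while keeping particle
counts tractable at 50–150 molecules/µm².  The particle number in the
patch is fixed for the duration of a trace (drawn once), which
suppresses the amplitude by the canonical-ensemble factor
$1 - A_{\mathrm{eff}}/A_{\mathrm{box}} \approx 0.5\,\%$ — negligible.

What the generator deliberately does **not** emulate: photophysics
(blinking, triplet states, photobleaching during acquisition), detector
afterpulsing, 3D diffusion or flow, realistic confocal point-spread
functions beyond the 2D Gaussian, membrane topography, and any biology of
the dissociation process beyond a programmed piecewise-linear transient
(`dissociation_schedule()`, with dissociated complexes converted to equal
increments of the single-color species so label totals are conserved).
Passing tests therefore certify the *analysis chain* under the model's
own assumptions; they cannot certify robustness to the photophysical and
optical artifacts of real recordings, which is exactly why the screening
and QC layers exist.

`simulate_frap_record()` generates two-phase association recoveries with
a mobile and an immobile pool, whole-field decay and Gaussian noise, with
the first post-bleach frame sampled exactly at the bleach (so the $I_0$
convention above is unbiased).

# Problem sizes and numerical choices

The validation suites run the full chain on deliberately modest problem
sizes, chosen to exercise every estimator at realistic signal-to-noise:
single-cell acquisitions of 30–60 s at 1-ms bins (3–6 segments of 10 s),
batches of 6–10 cells per scenario, concentrations of 50–140
molecules/µm², crosstalk 5 %, and FRAP grids of 100 records per
condition.  Multi-start counts, optimizer iteration caps and bounds are
stated in the function documentation.  Ties and degenerate inputs follow
one rule: reject loudly (all-zero traces, zero reference points,
crosstalk-saturated red channels), never guess.

# Known limitations

- Per-cell crosstalk estimates from 30-s controls are noise-dominated;
  only the median across a control batch is meaningful (that is the
  procedure's own design).
- The dimer fraction from the global fit has a one-sided soft floor:
  since concentrations cannot be negative, noise pushes a genuinely
  all-dimer population a few percent below 1 on average.
- The focal-displacement range (100–150 nm) leaves a ~20 % slack on the
  cross-amplitude scale that propagates into mixed-dimer concentrations;
  this mirrors the instrument calibration uncertainty, and is the reason
  the dynamic analyses work with relative series only.
- The FRAP two-phase fit is descriptive; no diffusion coefficient is
  derived from recovery curves.
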