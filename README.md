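# dimerscope

Quantifying cell-surface receptor dimerization — and its dynamics — from
two-color live-cell fluorescence data.

## The problem

Whether a membrane receptor such as a Class F GPCR travels alone or as a
dimer is invisible to plain imaging, but it leaves two quantitative
fingerprints when the receptor is co-expressed as a green (GFP) and a red
(mCherry) fusion:

- **Co-diffusion.** In fluorescence cross-correlation spectroscopy (FCCS)
  the photon streams from a diffraction-limited membrane spot are
  correlated; dual-labeled complexes produce a cross-correlation
  amplitude, and the three curves \(G_G, G_R, G_{GR}\) together determine
  the surface concentrations \(c_g, c_r, c_{gr}\) of green-only,
  red-only and complexed receptors diffusing in 2D:

  \[ G_G(\tau)-1 = \frac{A_G\,(x_g^2 c_g\,\mathrm{Diff}^G_g(\tau) +
     c_{gr}\,\mathrm{Diff}^G_{gr}(\tau))}{(A_G(x_g c_g + c_{gr}) + BG_G)^2},
     \qquad \mathrm{Diff}^G_u(\tau) = \Big(1 + \tfrac{4D_u\tau}{\omega_G^2}\Big)^{-1} \]

  with analogous red and cross terms, spectral crosstalk \(K\), and a
  displacement factor
  \(\exp(-2r_0^2/(\omega_G^2+\omega_R^2+8D_{gr}\tau))\) for imperfect
  focal overlap.  Fitted concentrations are then compared with the
  **random-pairing model**: if all receptors are dimers with \(M\) green
  and \(N\) red protomers pairing at random, the mixed-dimer probability
  is \(p_{gr} = 2MN/((M+N)(M+N-1))\) and the expected mixed-dimer
  concentration \(c'_{gr} = p_{gr}(c_{gg}+c_{gr}+c_{rr})\).

- **Co-immobilization.** In dual-color FRAP, antibody-crosslinking the
  red population anchors it; an interacting green partner then loses part
  of its mobile fraction \(F_m = (I_P - I_0)/(I_I - I_0)\).

dimerscope implements both analysis chains end to end — multiple-tau
correlation with segment screening, the two-step control/measurement
global fit with QC, dimer combinatorics, crosstalk-corrected dynamic
(time-lapse) bound-fraction series, and FRAP normalization/screening —
plus a seeded Brownian-dynamics generator of synthetic two-channel traces
and FRAP records used to validate every estimator against ground truth.

## Worked example

```r
library(dimerscope)

geom <- detection_geometry(omega_g = 222, omega_r = 272, r0 = 120)  # nm

# a fully dimerized population: 50 complexes/um^2, 5 % crosstalk
truth <- species_model(c_gr = 50, D_gr = 0.25, K = 0.05)
trace <- simulate_membrane_traces(truth, geom, duration = 60,
                                  dt = 1e-3, box_size = 3, seed = 42)
curves <- fccs_curves(trace, segment_length = 10)   # screened 10-s segments
fit <- fit_dimerization(curves, geom, K_fixed = 0.05)
fit
```

```
FCCS global fit (x_g = 1, x_r = 1)
  c_g = 2.97, c_r = 0.722, c_gr = 50.3 /um^2 (dimer fraction 0.932)
  D_g = 0.00984, D_r = 0.00334, D_gr = 0.271 um^2/s; K = 0.0500; r0 = 117.6 nm
  R^2: GG 0.988, RR 0.992, GR 0.987
```

The fit reads the trace back as ~93 % dimer at the true complex
concentration (50.3 vs 50 µm⁻²) and the true complex diffusion
coefficient (0.27 vs 0.25 µm²/s); the residual few percent assigned to
single-color species is the expected one-sided noise floor
(concentrations cannot be negative).  The mobile-fraction side:

```r
rec <- simulate_frap_record(F_m = 0.8, noise_sd = 2, seed = 7)
mobile_fraction(normalize_recovery(rec))
```

```
Mobile fraction F_m = 0.797 (I_I = 1.000, I_0 = 0.170, I_P = 0.832)
```

## The analysis workflow

Numbered drivers under `analysis/` rebuild the full synthetic study and
write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_cells.R` | simulate control + measurement cells, write TSV traces |
| `02_fit_fccs.R` | two-step global fit (control median K, then dimer fits + QC) |
| `03_dimer_model.R` | random-pairing model comparison, RMS per scenario |
| `04_dynamics.R` | programmed dissociation transient, normalized N_gr/N_r series |
| `05_frap.R` | dual-color FRAP batch: mobile fractions, screens, two-phase fits |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate_cells.R`.

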