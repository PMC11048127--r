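---
title: "Modelling the evaporation-endpoint microwave WBC assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evaporation-endpoint microwave WBC assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evapsense)
```

## The assay and why it needs an endpoint

A printed LC resonator senses the permittivity of whatever sits in its
fringing field: extra permittivity raises the effective capacitance and
pulls the resonant frequency `f0 = 1/(2π√(LC))` down. White blood cells
in buffer, however, are nearly invisible to a GHz field. At the
operating band (well above 100 MHz) the membrane capacitance is
effectively short-circuited, so the field probes the cytoplasm — and a
living cell keeps its cytoplasm isotonic with the surrounding PBS, so
suspension and buffer look dielectrically alike. The assay therefore
waits: after a 1 µL droplet dries (about ten minutes), only the
deposited cells remain, their interiors no longer exchange material
with a bath, and the dried deposit perturbs the resonance in proportion
to the number of cells. The endpoint resonant frequency falls linearly
with concentration, and inverting that line counts cells.

This vignette records the models the package implements, the
parameters that matter, what the synthetic-data generators do and do
not emulate, and the numerical and design decisions taken where more
than one defensible choice existed.

## Resonator circuit model

The spiral-inductor closed form is the standard current-sheet
approximation,

$$L = \mu_0 n^2 d_{avg} \frac{c_1}{2}\left[\ln\frac{c_2}{\rho} + c_3\rho + c_4\rho^2\right],
\qquad \rho = \frac{d_{out}-d_{in}}{d_{out}+d_{in}},$$

with the circular layout preset $(c_1,c_2,c_3,c_4) = (1.00, 2.16,
0.00, 0.20)$. The fill ratio is dimensionless and scale-invariant;
$\rho = 0$ (a vanishing annulus) makes the logarithm diverge and is a
domain error rather than a large number.

The interdigital ("circinate") capacitor uses the conformal-mapping
result for coplanar electrodes. With modulus $k = a/b$ and
$k' = \sqrt{1-k^2}$,

$$C = \left[\varepsilon_0\,\frac{1+\varepsilon_{sub}}{2}\,
\frac{K(k')}{K(k)} + \varepsilon_0\,\frac{t}{a}\right] L_C,$$

where $K$ is the complete elliptic integral of the first kind
(`pracma::ellipke`), $\varepsilon_{sub} = 12.85$ the GaAs relative
permittivity, $t$ the SiNx thickness and $L_C$ the total finger
length. **Design note:** published transcriptions of this formula in
the application literature are frequently garbled; the form above is
the standard half-space result (air above, substrate below averages to
$(1+\varepsilon_{sub})/2$) plus a single thin-film correction
$\varepsilon_0 t/a$, chosen because it preserves the two structural
facts every transcription agrees on — the $K(k')/K(k)$ ratio and
strict linearity in $L_C$ — while being dimensionally consistent. The
implementation is pinned by a frozen arbitrary-precision evaluation of
exactly this algebra, so any accidental change to the parse fails a
regression test.

Parasitics ($C_{SiNx}$, the inter-turn fringing $C_{ab}$, the
substrate shunt $C_{sub}$/$R_{sub}$) appear in the equivalent circuit
of such chips but have no published closed forms for this layout
family; `circuit_params()` therefore folds user-supplied values into
the total capacitance instead of deriving them from geometry.

The fabricated layout behind the real chip's 1.28 GHz operating point
is not public, so that frequency is used only as a synthetic `f0`
(`default_chip_circuit()` picks the conventional 5 nH split); no claim
is made that the design equations reproduce it.

### S11 synthesis and resonance extraction

The one-port reflection response is the standard one-pole model seen
through a coupling factor $g$:

$$S_{11}(f) = \frac{\Gamma_0 + 2jQ\delta}{1 + 2jQ\delta},\qquad
\delta = \frac{f-f_0}{f_0},\qquad \Gamma_0 = \frac{1-g}{1+g}.$$

It is passive everywhere, dips exactly at $f_0$, and nulls completely
at critical coupling $g = 1$. Extraction refines the grid minimum of
$|S_{11}|$ by parabolic interpolation of the log-magnitude through the
three surrounding points (ties between equal adjacent minima break
toward lower frequency, for determinism), and estimates the loaded Q
from the half-reflected-power bandwidth — the band edges where
$|S_{11}|^2$ rises halfway from its minimum toward 1, which for the
model above sit exactly at $f_0(1 \pm 1/2Q)$. On the default VNA grid
(10 001 points, 0.0001–3.0001 GHz in 0.0003 GHz steps, the instrument
sweep the assay uses) the round trip recovers $f_0$ to well under half
a grid step and Q to well under 5 %.

## Dielectric models

**Penetration depth.** The field-power decay length in a lossy
dielectric is

$$D_p = \frac{\lambda_0}{2\pi\sqrt{2\varepsilon'}}
\left[\sqrt{1+\left(\tfrac{\varepsilon''}{\varepsilon'}\right)^2}-1\right]^{-1/2}.$$

The squared loss-tangent radicand is the only dimensionally consistent
reading of this classic formula (transcriptions sometimes drop the
exponent), and the implementation is pinned against its low-loss limit
$\lambda_0\sqrt{\varepsilon'}/(2\pi\varepsilon'')$. A lossless medium
returns an explicit `Inf` sentinel rather than a large number, so
downstream code can branch unambiguously.

**Single-shell cell.** A cell is a cytoplasm sphere ($\varepsilon_i$)
in a thin membrane shell ($\varepsilon_{mem}$, thickness $d \ll R$):

$$\varepsilon_P = \varepsilon_{mem}
\frac{\gamma^3 + 2A}{\gamma^3 - A},\qquad
A = \frac{\varepsilon_i-\varepsilon_{mem}}{\varepsilon_i+2\varepsilon_{mem}},\qquad
\gamma = \frac{R}{R-d},$$

computed in complex arithmetic throughout. Both algebraic limits
($d=0$ and $\varepsilon_{mem}=\varepsilon_i$ collapse to
$\varepsilon_i$) are exact to rounding. No measured membrane/cytoplasm
permittivities exist for the K562 line; the defaults in
`default_run_config()` (6 and 60) are explicitly labelled placeholders
in the range reported for comparable mammalian cells.

**Effective medium.** Concentration-to-permittivity mapping uses
Maxwell–Garnett mixing for spherical inclusions, which is exact at
both volume-fraction endpoints and monotone between them; a linear
volume-weighted rule sits behind a config switch purely for
sensitivity analysis. The choice is a stated assumption — the assay
narrative only asserts that more deposited material means higher
surface permittivity, without a mixing rule.

**Frequency regimes.** `dispersion_regime()` encodes the four bands of
the suspended-cell equivalent circuit with edges at 1 kHz, 1 MHz and
100 MHz. Bands are half-open `[low, high)` so a frequency exactly on
an edge classifies deterministically into the higher band.

## Sample geometry

All of this is exact arithmetic, kept separate so its conventions are
visible: counts are `concentration × volume` (250…8000 cells for the
1 µL doubling ladder); the monolayer capacity divides the 1 mm² chip
by the unrounded cell cross-section $\pi(7.5\,\mu m)^2$, giving
5658.8 (quoted as 5660 at 3 s.f.) — note the deliberately reported
companion figure ≈ 5556 that results from using the 2 s.f.
cross-section $1.8\times10^{-10}\,m^2$ instead; the package always
computes with the unrounded value and treats the capacity as a lower
bound (real cells squeeze). Stack heights generalise the published
two-cell estimate: `layers = ceiling(count/capacity)`, lower bound
`min(layers, 2)` membrane thicknesses (each interface flattened to a
membrane, floored at the two-membrane case), upper bound
`layers × diameter` (undeformed spheres). The 10 nm default membrane
thickness is back-derived from the 0.02 µm two-membrane floor and
flagged as inferred, overridable in config.

## Synthetic data: what it emulates, and what it does not

`simulate_endpoint_dataset()` draws replicate endpoint frequencies
from the configured affine law with multiplicative Gaussian noise,
`f = line(x)·(1 + N(0, 0.038))`. The defaults *are* the study
conditions: the reference line (slope −0.02506×10⁻⁶ GHz per cells/mL,
intercept −1.65475 GHz), the six-step doubling ladder, three
replicates, and relative SD 3.8 % — the quoted replicate-scatter
bound. The multiplicative form matches the relative phrasing of that
bound; an additive option exists in the trace simulator for
comparison. Note the 3.8 % scale is large relative to the line's total
span (~0.2 GHz over the ladder), so single-dataset slope estimates
carry ~20 % relative standard errors; recovery tests are therefore
statistical (standard-error bands over many seeds), not point checks.

`simulate_evaporation_trace()` renders the characteristic trajectory:
an exponential solvent-volume decay reaching 1 % at `dry_time` (600 s
by default — "about ten minutes"; a linear option exists), a solute
volume fraction that rises as solvent leaves, Maxwell–Garnett mapping
to a rising surface permittivity, and a capacitance-loading map
`f0 = f_bare/√(1 + κ(ε_surf − 1))`. At `dry_time` the permittivity
collapses to the dry-residue value `1 + (residue_eps_scale − 1) ×
coverage` and the frequency jumps upward between samples (the real
transition is too fast to record manually) to a plateau that decreases
with concentration. Coverage is deliberately *not* capped at one
monolayer, so stacked deposits keep the plateau strictly monotone in
concentration. A pure-PBS run plateaus at a configured permittivity
constrained to lie strictly between the 1×10⁶ and 2×10⁶ cells/mL
residues, reproducing the observed ordering of dried buffer.

The κ coefficient (default 0.02) is a dial, not physics: it is chosen
once so traces span a plausible band below the 1.28 GHz bare-chip
point. Likewise `eps_wet = 76` (PBS near 1 GHz), `eps_solute = 100`
and `residue_eps_scale = 12` are monotone placeholders — no one has
measured the permittivity of a dried WBC deposit. Consequently,
passing tests demonstrate that the *pipeline* (trace → jump detection
→ endpoint → fit → inversion) is correct and self-consistent under the
qualitative structure of real traces; they do not validate the
magnitudes of real dry-residue dielectrics, evaporation physics
(diffusion, humidity, coffee-ring deposition), or cell deformation.
The real assay's own r² values (0.99748 / 0.98464 — the two published
figures disagree) are carried as metadata on
`reference_calibration()`, not recomputed: the per-replicate raw data
behind them were never published.

## Calibration and inversion

`fit_calibration()` is ordinary least squares with replicates entering
individually (all information used; per-concentration means are one
flag away, and coincide exactly in the noiseless case). r² is the
squared Pearson correlation of observed and fitted response.
Sensitivity is `|slope| × 10⁹` Hz per cells/mL — sign-insensitive,
since the line's sign convention (the published intercept is negative
even though frequencies are positive, because the response is framed
as a shift) is left to the user; the package treats the curve as an
abstract affine map.

Inverse prediction uses the first-order (delta-method) interval,

$$\hat x = \frac{y-b}{m},\qquad
\mathrm{Var}(\hat x) \approx \frac{s^2}{m^2}
\left(1 + \frac1n + \frac{(\hat x - \bar x)^2}{S_{xx}}\right),$$

with a t quantile on n−2 degrees of freedom — the smallest defensible
method for a six-point calibration; no Bayesian machinery. Negative
estimates are clipped to zero and flagged, never silently returned,
and the unclipped value is retained. A slope below tolerance raises a
non-invertible-calibration error. Simulated at the 3.8 % noise scale,
the nominal 95 % intervals cover truth at very close to nominal rate
(the test suite checks 93–97 % over 1000 seeded runs).

## Numerical choices and problem sizes

* Frequencies are Hz internally, GHz at user surfaces; the conversion
  is centralised.
* Physical constants: µ₀ and c at CODATA 2018; ε₀ carried at the
  conventional engineering value 8.854×10⁻¹² F/m so capacitances match
  hand calculations at that precision.
* Passivity and grid-uniformity checks on sweeps use relative
  tolerances of 10⁻⁹ and 10⁻⁶; the dB floor for log-magnitude work is
  10⁻¹⁵ (≈ −300 dB), which keeps the critical-coupling null finite.
* Jump detection in `endpoint_from_traces()` requires the largest
  increment to be positive and to exceed 3× the 90th percentile of all
  other absolute increments, with ≥ 3 plateau samples after it — this
  rejects truncated traces and is insensitive to wet-segment drift.
* Monte-Carlo sizes are chosen to keep the full suite around ten
  seconds while leaving the statistical checks well-powered: 100-point
  random sweeps for the closed-form cross-checks, 50 resonance
  round-trip points, 200 datasets for slope recovery, 1000 for
  interval coverage. The same sizes are used by
  `scripts/acceptance.R`.

## Known limitations

* The design equations cannot reproduce the fabricated chip's
  operating point — its geometry was never published — and no
  full-wave (HFSS-class) electromagnetic solver is wrapped or
  emulated.
* No Cole–Cole/Debye dispersion fitting, no temperature dependence
  (the assay holds 26.00 ± 0.40 °C and reports no effect), and no
  explicit conductivity term (the VNA drive is weak enough that medium
  conductivity is negligible).
* Evaporation is kinematic, not physical: no droplet spreading,
  contact-angle, humidity coupling or spatial deposition patterning.
* The dry-residue permittivity model is a monotone placeholder
  constrained only by the qualitative orderings described above.
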