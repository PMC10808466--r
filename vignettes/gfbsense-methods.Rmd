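---
title: "Models and methods behind gfbsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gfbsense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfbsense)
```

`gfbsense` implements the computational core of a two-channel
epifluorescence sensing system for membrane-based filtration barriers on
chip (the motivating device is a glomerulus-on-chip: a capillary channel
and a filtrate channel separated by a 20 µm track-etched polycarbonate
membrane, perfused with dye-conjugated tracers such as inulin-FITC and
HSA–Texas Red). This vignette records the models, the tunable
parameters, the numerical choices, and the places where the design was
genuinely open — together with the reasoning behind each choice.

## 1. Intensity-to-concentration calibration

### The 4PL model

Mean ROI pixel intensity responds sigmoidally to tracer concentration
and is modelled by the four-parameter logistic

$$F(x) = d + \frac{a - d}{1 + (x/c)^b}$$

with $x$ the concentration (mg/mL), $a$ the minimum asymptote (AU), $d$
the maximum asymptote (AU), $c$ the half-maximal concentration (mg/mL)
and $b$ the Hill slope. At $x = 0$ we take the limit $F(0) = a$ when
$b > 0$; negative $b$ is allowed, in which case the model is invariant
under $(a, b, c, d) \mapsto (d, -b, c, a)$ and the asymptote roles swap
(the $x \to 0$ asymptote becomes $d$). Code that needs a unique
representation canonicalizes to $b > 0$.

### Fitting

`fit_4pl()` minimizes summed squared intensity residuals on the linear
intensity scale with `nls()` (port algorithm, bounded so $c > 0$),
multi-started from $a = \min(y)$, $d = \max(y)$, $c$ at the geometric
mean of the concentrations and $b \in \{\pm 0.5, \pm 1, \pm 2\}$; the
converged start with the lowest RSS wins. The reference workflow used a
commercial fitter whose initialization is not documented, so the
multi-start is this package's own choice; the test suite cross-checks
it against an independent grid-search minimizer (profiling $(b, c)$ on
a grid and solving the asymptotes, which enter linearly, by least
squares).

The port algorithm is also the reason noiseless (zero-residual) data
fit cleanly, which the exact-recovery tests rely on.

95% confidence intervals come from the asymptotic, Jacobian-based
covariance of the fit ($\pm t_{0.975,\,n-4}\,\mathrm{se}$). The
reference report does not state its CI method (profile likelihood would
be the main alternative); asymptotic intervals were chosen because they
are defined for every converged fit and are what the downstream
sensitivity-region construction needs. The Monte-Carlo coverage test
(100 seeded trials at σ = 2 AU) confirms ≥ 95% coverage for $c$ under
the stated noise model, so the approximation is adequate in the regime
the sensor operates in.

### Inversion, error propagation, sensitivity region

`invert_4pl()` applies the closed form
$x = c\,((a-d)/(f-d) - 1)^{1/b}$, defined for intensities strictly
between the asymptotes. Out-of-range intensities raise a typed
condition carrying which asymptote was violated; the library never
clamps silently, because a clamped reading is a scientific statement
(saturation, or signal below the floor) the caller must handle
explicitly.

`concentration_error()` reverse-maps the standard error of the
regression through the inverse curve as the symmetric half-width
$|x(f+\mathrm{se}) - x(f-\mathrm{se})|/2$. The symmetrization is a
design choice (the source procedure says only that the standard error
is reverse-mapped); near an asymptote, where only one side is
invertible, the one-sided distance is returned and flagged.

`sensitivity_region()` inverts the interior-side 95% CI edges of the
two asymptotes: the edge of the $x \to 0$ asymptote facing the other
asymptote gives the lower concentration bound, and vice versa. A
zero-width CI (noiseless fit) makes an edge numerically
indistinguishable from its asymptote; the bound is then reported as 0
or ∞ and flagged unbounded rather than erroring, since this is a
legitimate degenerate limit.

### Flat-field correction

LED illumination is uneven across the field of view. From ≥ 3 frames at
one uniform concentration, the per-pixel multiplier is

$$m_{ij} = \frac{\overline{\bar{P}}}{\bar{P}_{ij}}$$

(global mean of the pixelwise-mean image over its pixelwise mean).
Applying $m$ flattens the calibration image exactly (spatial CV below
1e-9 in the tests) while preserving its global intensity level. A
strict "multipliers average to 1" convention is *not* used: for a
non-flat field the mean of $\overline{\bar{P}}/\bar{P}$ exceeds 1 by
Jensen's inequality, and rescaling to unit mean would shift the
corrected intensity level away from the calibration level, breaking
curve inversion. One mask is estimated per LED channel, because each
LED has its own illumination field. All corrected frames are floats;
8-bit quantization exists only at frame ingestion.

## 2. Frame quantification

`analyze_timeseries()` is the acquisition loop: per frame, subtract the
channel's background (clipping at zero — 8-bit data cannot represent
negative light), apply the channel's mask, take the capillary and
filtrate ROI means, and invert the channel's curve. Masking precedes
ROI averaging, matching the stated order of the reference pipeline
(the mask "is applied to each image collected").

Two percentages are reported: the diffusion percentage proper,
$100 \cdot C_{f}/C_{i,\mathrm{capillary}}$ with the *initial* capillary
concentration as denominator, and an instantaneous variant against the
current capillary reading, which is the quantity that approaches the
equilibrium ratio during gradient steps. The filtrate/capillary
intensity ratio is kept as the hardware-stability QC (≈ 1 under equal
loading).

Out-of-range and saturated points are flagged (`below_range`,
`above_range`, `saturated`) and retained with `NA` concentrations;
points are never dropped. Saturation means > 1% of an ROI's raw pixels
at 255. ROI rectangles use 0-based half-open indexing, the convention
of the acquisition software the package interoperates with.

`acquisition_schedule()` encodes LED cycling: channels fire one at a
time in fixed order (cyan 490 nm before amber 590 nm, preventing
spectral crosstalk), all events of a cycle share the cycle's nominal
time point, and the period is validated against a configurable hardware
floor (default 7 s).

## 3. Transport model

The chip physics is a deliberately lumped, unit-explicit chain:

* **Shear stress** (cgs): $\tau = 6 Q \mu / (w h^2)$ — poise, cm,
  mL/s → dynes/cm².
* **Hydrostatic pressure** (cgs → Pa):
  $\pi_{hs} = 0.1\,(\rho g h - \tfrac12 \rho v^2)$, the 0.1 converting
  barye to Pa; negative values at high velocity are reported as-is.
* **Osmotic pressure** (van 't Hoff): $\pi_{osm} = MRT$ in atm,
  × 101325 to Pa. Molarity is $C_0$ (mg/mL ≡ g/L) over the tracer's
  molar mass; whether the free or conjugated molecular weight is used
  is a tracer configuration field, since the reference text does not
  say which it used.
* **Darcy flux**: $j = \kappa \Delta P / (\mu h_m)$ with κ in µm²,
  µ in Pa·s, membrane thickness in µm → µm/s.
* **Total flux**: the printed form multiplies $j$ by the area "in cm²"
  with a $10^{-12}$ µm³→mL factor; dimensional consistency requires the
  area in µm² first, so the implemented net conversion is
  $J = j \cdot A \cdot 10^{-4}$ mL/s. This reconciliation is a
  deliberate reading, tested dimensionally.
* **Steady state**: $C_f = J C_0 (V_c/Q) / V_f$ — mass flux times
  membrane exposure time over filtrate volume.
* **Transient**: $c_f(t) = a + b(1 - e^{-t/\tau})$ with τ = 120 s by
  default (literature-derived for comparable lumped systems),
  overridable everywhere it appears.

Three distinct symbols named *h* in the source formulas (flow-channel
height, capillary column height, membrane thickness) are separate named
fields, as are the two τ's (shear stress vs. time constant) and the two
$(a, b)$ pairs (4PL vs. transient), which live in different types.

`estimate_permeability()` inverts the chain for κ, which enters
linearly at fixed ΔP, so the inversion is exact
(round trip to 1e-9 over three decades in the tests). The reference
measurement perfused 0.1 mg/mL for 30 min at 100 µL/min — 15 time
constants, effectively steady state — so the default treats the
measured concentration as the equilibrium value; an optional
`perfusion_time_s` de-attenuates a reading taken earlier by
$1 - e^{-t/\tau}$.

### Geometry defaults

The reference text prints the membrane thickness (20 µm) and layer
stock (1/16″ channel layers, 3 mm filtrate assembly) but the absolute
channel width, area and volumes live only in fabrication design files
that are not bundled. The shipped `chip_default.json` is therefore a
**documented synthetic stand-in**: heights from the stated stock, the
channel width back-calculated from the device's published wall shear
stress (30.7 × 10⁻³ dynes/cm² at 100 µL/min), and a 4 cm exposed
channel length assumed for area and volumes. Geometry is never
hard-coded in functions — every model call takes a `chip_geometry`.

A consequence worth stating plainly: with this stand-in geometry the
steady-state prediction at $C_0 = 0.1$ mg/mL and 8 µL/min is
≈ 0.014 mg/mL, not the 0.0344 mg/mL the reference device reports for
its own geometry. Separately, the reference's printed triple
(0.0344 / 0.18 / 0.24 mg/mL for $C_0$ = 0.1 / 0.2 / 0.4) implies
diffusion fractions of 34% → 90% → 60%, which is non-monotone in
$C_0$ — but the model's fraction is provably monotone increasing in
$C_0$ (the only $C_0$-dependence of $C_f/C_0$ is the osmotic term,
which grows with $C_0$). No single configuration of this equation chain
reproduces all three printed values; the corresponding device-level
check in the test suite is intentionally left failing as an honest
record of that gap.

## 4. The synthetic chip

The simulator exists so the full pipeline is testable without hardware.
`render_frame()` builds the ideal image (each ROI at the 4PL intensity
of its concentration, background at the curve floor $a$), adds an
optional stray-light offset, divides by the truth mask (the mask is the
*correction*, so the raw field is its reciprocal), adds noise, and
quantizes to 8 bits with clipping. Noise defaults to Gaussian read
noise of σ = 1 AU with no Poisson term — a plain model for an 8-bit
camera binned eight times; the reference gives no noise model, and shot
noise is available but off by default. Frames default to the binned
507 × 380 sensor resolution; tests use smaller frames because no
result depends on frame size.

`simulate_experiment()` drives piecewise first-order dynamics: at each
segment boundary the filtrate trajectory restarts from its current
value toward the new segment's steady-state prediction, with step
changes treated as instantaneous (matching how the reference fits its
injections). The equilibrium is capped at the commanded capillary
concentration — passive diffusion cannot overshoot its source — and
the capillary ground truth is the commanded value (closed-loop
reservoir dilution is out of scope). Every generator is deterministic
under a fixed seed, and seeding is local: generators never perturb the
caller's RNG stream.

What a green end-to-end test establishes: that calibration, masking,
background subtraction, inversion and the transport chain compose
correctly under the stated noise model. What it does not establish:
performance under real optics (PSF blur, spectral crosstalk, vignetting
beyond the empirical mask, dye bleaching, reservoir depletion) — none
of which the simulator emulates.

## 5. Interfaces and formats

Frames travel as 8-bit grayscale PNG plus a manifest CSV
(`filename, channel, timestamp_s`); no TIFF codec is available in this
toolchain, and PNG is the other format the reference acquisition stack
supports. Masks are float-valued and stored as plain-text TSV
matrices. Curves serialize to JSON with all fit metadata; calibration
data as CSV (`concentration_mg_per_ml, replicate, intensity_au`); time
series as CSV with a fixed, documented column order, 9 significant
digits, LF endings. Configurations are JSON or YAML with unit-bearing
field names and unit-string normalization for flowrates
(`"8 uL/min"` → 1.3333e-4 mL/s). A thin CLI
(`inst/cli/gfbsense`: `calibrate`, `analyze`, `simulate`, `predict`,
`shear`) wraps the package functions; every subcommand is a pure
function of (config, inputs, seed).

## 6. Known limitations

* The transport model is lumped: no spatial concentration profile, no
  Fickian PDE, no cellular-layer resistance. It is the model the
  reference system itself uses, and it is exact only in that idealized
  world.
* The shipped geometry is a stand-in (see §3); absolute concentration
  predictions depend on it linearly through $A V_c / V_f$ and should
  not be compared against a physical device without measured geometry.
* Asymptotic CIs can undercover for very small or very noisy
  calibration designs (< 8 concentrations, single replicates); the
  Monte-Carlo tests pin coverage only for the stated designs.
* The 4PL fit is identifiable only when the data bracket the inflection
  region; serial dilutions spanning well past both asymptotes (the
  reference spans 0.0001–5 mg/mL) are assumed.
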