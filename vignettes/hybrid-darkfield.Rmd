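---
title: "Single-shot dark-field and hybrid contrast retrieval: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-shot dark-field and hybrid contrast retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eidark)
```

## The convolution model

Edge-illumination imaging records, per detector pixel, an *illumination
curve* (IC): the intensity as the sample mask is translated through one
period. The package models the empty-beam curve as a Gaussian with area
`A`, centre `x0` and variance `sigma_r2` (µm²), optionally plus a small
additive `offset` that stands in for the heavier-than-Gaussian tails of
real curves. The physical origin of that tail excess is not well
understood; it is deliberately modelled as nothing more than an additive
constant, fitted only on request (`with_offset = TRUE`), and defaults to
zero (ideal masks).

A sample rescales the curve area by the transmission `t`, shifts its centre
by the refraction displacement `dx_ref` and broadens its variance by the
scattering (dark-field) signal `sigma_o2`. All three are per-pixel maps;
`ic_sample()` is exactly this three-parameter model and the forward
simulator (`simulate_frames()`) does nothing else — no detector PSF, no
polychromatic spectrum, no mask imperfections.

### Units

The dark-field signal is a variance. At the detector-mask plane it has
units of length² (µm²); dividing by the squared propagation distance (the
sample-mask-to-detector-mask distance, 165 mm for the laboratory preset)
turns it into a geometry-independent angular variance (µrad²). Retrieval
math runs in **mrad²** for variances and **mrad⁻²** for the
attenuation-to-scattering ratio γ, because γ is naturally quoted in mrad⁻²;
µm² is treated as a presentation unit and converted at module boundaries
(`variance_um2_to_mrad2()` and friends). Keeping a single canonical unit
inside `hybrid_solve()` avoids the easiest mistake in the whole method:
mixing µm² and mrad² in the quadratic's coefficients.

The propagation distance convention deserves one note: the sample sits just
behind the sample mask, so the package uses the full mask-to-mask distance
(165 mm) for all conversions. This single convention reproduces both
printed sanity checks (a 2 µm shift ↔ 12 µrad; 4 µm² ↔ ~147 µrad²), which
is why it was adopted.

## Why single-shot works at the IC peak

At the peak, sensitivity to a lateral shift vanishes to first order (it is
proportional to the curve gradient), while sensitivity to attenuation and
broadening is maximal. `sensitivity_curves()` quantifies this with finite
perturbations. Two honest caveats, both visible in the implementation:

* with a *finite* shift the intensity change at the peak is small but not
  exactly zero — a 2 µm shift on the `sigma_r2 = 81` µm² reference curve
  drops the peak by ~2.4%, indistinguishable from ~4.1 µm² of scattering.
  The package treats this as the quantitative bound on the
  refraction-neglect error, and the retrieval flags cannot detect it;
* the per-channel normalization matters. Normalizing the absolute intensity
  change by the reference curve value makes the attenuation channel exactly
  flat in `xbar`, which contradicts the qualitative "highest at the peak"
  description; the default therefore normalizes each channel's absolute
  change to its own maximum, and `normalize = "reference"` provides the
  literal ratio formula for comparison.

## The hybrid retrieval

With `Omega = (Ir/Is)^2` measured at the peak and refraction neglected,

* pure-phase objects (`t = 1`): `sigma_o2 = sigma_r2 * (Omega - 1)`;
* attenuating objects need one more relation. Macroscopic homogeneity
  supplies it: `gamma = mu/eps` constant across the sample, hence in
  projection `gamma = -ln(t) / sigma_o2`. Expanding `-ln(1-a)` to second
  order gives `sigma_o2 = (a + a^2/2)/gamma`, and substitution into the
  single-shot relation yields the quadratic implemented in
  `hybrid_solve()`:

  `(G - 1/2) a^2 - (2G + 1) a + (G - gamma*sigma_r2) = 0`,  `G = gamma*sigma_r2*Omega`.

A note on this equation: naive transcription of the coefficients as
"γΩ − 1/2" etc. is not dimensionally consistent (γΩ carries mrad⁻²). The
form above is the algebraic re-derivation from the three ingredient
equations; it is verified in the test suite by a round-trip property
(forward-generate Ω from any `(a, gamma, sigma_r2)`, solve back, recover
`a` to < 1e-9 over a 1200-point grid) and by its γ → 0 limit.

### Numerical choices

* **Root branch.** The physical root is the negative-square-root branch. It
  is evaluated as `a = 2C / (B + sqrt(B^2 - 4AC))` rather than the textbook
  form: this is exact, avoids cancellation for small signals, and stays
  finite when the leading coefficient `G - 1/2` crosses zero.
* **γ = 0** is handled as the exact pure-phase limit rather than a division
  by zero: `a = 0`, `sigma_o2 = sigma_r2*(Omega - 1)`.
* **Noise handling.** Noise can produce `Omega < 1` (negative retrieved
  variance) or a negative discriminant. Values are *preserved, not
  clamped*, with per-pixel integer flags (`retrieval_flags()`), so that
  noise in tomographic projections stays zero-mean; clamping would bias
  reconstructions. Negative discriminants return `a = 0` plus a flag.
* **Gaussian fitting** (conventional retrieval) uses `nls` (port) with
  moment-based starting values. On noise-free data the optimizer reports
  "singular convergence" at the zero-residual minimum; fits are accepted
  whenever the relative RMS residual is below 1e-6, and otherwise flagged
  `no_convergence` with the pixel's parameters replaced by the reference
  values so that one degenerate pixel cannot abort a full-field retrieval.
* **σr² is a global scalar by default.** Per-pixel reference variance maps
  are supported by fitting a reference stack, but constant σr² costs little
  accuracy and matches how the single-shot working point is set up.

### Estimating γ

`estimate_gamma()` works on a conventionally retrieved, fully sampled first
projection: pixels with `-ln t` above `mask_threshold` (default 0.01, a
repository choice — about 1% attenuation) enter the estimate. The default
estimator is the ratio of sums `sum(-ln t)/sum(sigma_o2)`, which weights
pixels by signal and is robust where per-pixel ratios blow up at low
attenuation; a `median_of_ratios` alternative is provided since "averages"
admits more than one reading. On a noise-free single-material projection
both recover μ/ε exactly.

## Tomography

The hybrid signal `(a + a^2/2)/gamma` equals `-ln(t)/gamma` up to the
truncated Taylor tail, so for a correctly chosen γ it is (approximately) a
line integral of ε and reconstructs cleanly with standard filtered back
projection. With a *wrong* γ the solved signal is a nonlinear function of
object thickness and FBP produces radial bias — cupping. `cupping_metric()`
quantifies this as the relative difference between the central disk and the
peripheral annulus of the (supposedly homogeneous) interior.

Implementation choices, all conventional:

* parallel-beam geometry throughout the synthetic stage (the laboratory
  magnification of 1.24 is a uniform scale factor at this scale);
* the Ram-Lak ramp filter is built from its sampled real-space impulse
  response, not as `|f|` on the DFT grid — the latter under-weights the
  lowest frequencies and biases the reconstructed mean by several percent
  (the uniform-cylinder test would catch it). A Shepp-Logan apodization is
  available;
* 360° scans are folded to 180° by averaging opposing rays (detector axis
  reversed), so redundant views are averaged rather than double-counted;
* dither step `d` occupies fine-grid columns `d, d + n_dither, ...`; the
  interleave order is recorded in the artifact metadata so real data can
  override it;
* flagged pixels enter FBP unclamped by default, for the same zero-mean
  noise argument as above.

## The synthetic world

The generator's defaults are the published laboratory system: masks with
79/98 µm periods and 10/17 µm apertures, 50 µm pixels, detector at 850 mm,
sample mask at 685 mm, and a typical per-pixel reference curve `A = 200`,
`sigma_r2 = 81 µm²` (σr ≈ 9 µm). Materials carry the printed
refractive-index parts at the Mo Kα design energy (17.48 keV, the
characteristic line of the molybdenum-anode source): polystyrene
δ = 1.37e-8, β = 5.35e-12; paper δ = 5.52e-7, β = 3.59e-10.

Where the stated world is silent, the package chooses once:

* **ε presets.** No linear scattering coefficient is printed for any
  material. The paper-wedge preset derives ε from the measured
  γ = 551 mrad⁻² (ε = μ/γ), making it internally consistent; the
  polystyrene ε (7e4 µrad²/m) is a synthetic fixture chosen so the 16 mm
  thick edge scatters a few tens of µm² — a plausible magnitude, not a
  reproduced value. The `benchmark_scatterer` material (μ = 2.6 m⁻¹,
  γ = 200 mrad⁻²) is likewise labelled synthetic.
* **Benchmark attenuation level.** The equivalence and cupping benchmarks
  use objects with a peak attenuated fraction of about 0.1 (t ≈ 0.9). This
  is fixed ex ante from the expansion's own error budget — the second-order
  Taylor error of `-ln(1-a)` is below 0.5% for `a ≤ 0.1` and grows to ~16%
  at `a = 0.6` — and matches the weak-attenuation regime in which the
  biological tomography demonstrations operate. The strongly absorbing
  regime (60% attenuation) is exercised qualitatively: there the naive
  `t = 1` retrieval is superlinear and overestimated, and the hybrid
  retrieval remains linear and close to the conventional signal, but no 1%
  agreement is claimed or tested.
* **Sensitivity perturbations** default to `t = 0.95`, `dx_ref = 1 µm`,
  `sigma_o2 = 4 µm²` — configuration, not claims.
* **Wedge thickness convention.** The printed thick-edge numbers (1.5%
  attenuation, t ≈ 0.99) are reproduced when the beam path at the thick
  edge spans the full 16 mm extent; that reading is adopted and
  `max_thickness_mm` is an explicit parameter.

### What a green test does not establish

The simulator draws from the same Gaussian convolution model the retrieval
inverts, so retrieval tests validate algebra and numerics, not physics.
Real data adds effects the model excludes by design: polychromatic spectra
and beam hardening (which would re-introduce cupping with an energy-dependent
ε), mask defects and per-pixel `x0`/`sigma_r2` variation, detector PSF and
cross-talk, refraction spikes at material boundaries (the simulator does
produce these via the δ gradient, but the retrieval ignores them), and
sub-resolution structure whose scattering is directional. Poisson noise is
the only stochastic ingredient.

## Known limitations

* Single global γ: multi-material samples yield a non-quantitative fused
  contrast (by design — that is the "hybrid" trade-off); reconstructed
  hybrid slices are labelled ε-equivalent, µrad²/m, and should not be read
  as quantitative dark-field or attenuation values.
* Second-order expansion only; strongly attenuating samples (a → 0.6)
  retrieve with percent-to-tens-of-percent bias. Higher-order terms would
  be a straightforward extension of `hybrid_solve()`.
* Parallel-beam FBP only; no iterative reconstruction, ring correction or
  beam-hardening model.
* Stacks, maps and sinograms travel as CSV + JSON sidecars. The metadata
  contract (axis order, IC positions, seed, config hash) is what other
  tools should rely on, not the container format.
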