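# eidark

Single-shot X-ray dark-field and hybrid attenuation/dark-field contrast
retrieval for edge-illumination imaging, with a forward simulator and a
parallel-beam tomography stage.

## The problem

Edge-illumination (EI) systems shape a laboratory X-ray beam into
independent beamlets with an absorbing *sample mask* and analyse each
beamlet with a second *detector mask*. Scanning the sample mask through one
period traces out, per pixel, an approximately Gaussian **illumination
curve** (IC)

```
Ir(x̄) = A / sqrt(2π σr²) · exp(−(x̄ − x̄0)² / (2σr²))
```

A sample modifies three things about this curve — and that is the whole
contrast model:

```
Is(x̄) = t·A / sqrt(2π(σr² + σo²)) · exp(−(x̄ − x̄0 − Δx̄)² / (2(σr² + σo²)))
```

* `t` — transmission (area reduction, attenuation contrast),
* `Δx̄` — lateral shift (refraction / differential phase),
* `σo²` — broadening (sub-resolution scattering: the **dark-field** signal,
  µm² at the detector-mask plane, µrad² after dividing by the squared
  propagation distance).

Conventional dark-field retrieval fits Gaussians to sampled ICs
(`N_IC × N_dither × N_proj` exposures for a tomography scan). This package
implements the much cheaper *single-shot* alternatives, which need only the
intensity at the IC **peak**, where refraction sensitivity vanishes to first
order and attenuation/scattering sensitivity is maximal. With
`Ω = (Ir/Is)²` measured at the peak:

* **pure-phase retrieval** (`t = 1`): `σo² = σr²(Ω − 1)`;
* **hybrid retrieval** for attenuating samples: assume *macroscopic
  homogeneity* — the ratio `γ = μ/ε` of linear attenuation to linear
  scattering coefficient is constant across the sample (mrad⁻²), so
  `σo² = (a + a²/2)/γ` with `a = 1 − t` the attenuated fraction (a
  second-order expansion of `−ln t / γ`). Substituting into the single-shot
  relation gives, with `G = γσr²Ω`, the quadratic

  ```
  (G − 1/2)·a² − (2G + 1)·a + (G − γσr²) = 0
  ```

  whose negative-square-root branch is the physical solution (it reduces to
  the pure-phase result at γ = 0). The resulting hybrid signal is a true
  line integral, so standard filtered back projection reconstructs it
  without the cupping artifacts the naive `t = 1` assumption produces on
  absorbing objects.

Everything needed to exercise this end to end is included: system geometry
and unit conversions, wedge and cylinder phantoms with printed
refractive-index presets, frame-stack simulation with dithering and Poisson
noise, all three retrieval paths, γ estimation from a fully sampled
projection, sinogram assembly, FBP, and a cupping metric.

## Worked example

The package's laboratory preset (detector at 850 mm, sample mask at 685 mm,
so a 165 mm propagation distance) and a typical reference curve with
`A = 200`, `σr² = 81 µm²`:

```r
library(eidark)
g <- ei_geometry()
p <- ic_params(A = 200, sigma_r2 = 81)

# a strong 2 um refraction shift barely moves the peak intensity...
pp <- peak_pair(p, sample_signals(dx_ref = 2))
100 * (1 - as.numeric(pp$sample) / pp$reference)
#> [1] 2.438902

# ...and is indistinguishable from ~4 um^2 of scattering
as.numeric(single_shot_purephase(pp$reference, pp$sample, 81)$sigma_o2)
#> [1] 4.100411

# in geometry-independent angular units:
shift_to_angle(2, g)        # 12.12121 urad
variance_to_angular(4, g)   # 146.9238 urad^2

# hybrid retrieval of a simulated attenuating wedge with its true gamma
m   <- material_preset("paper")             # delta, beta at Mo K-alpha
w   <- make_wedge(m, x_extent_mm = 14.8, max_thickness_mm = 1.66,
                  n_columns = 64, g = g)
Is  <- ic_sample(p$x0, p, w)
hy  <- hybrid_retrieve(array(ic_reference(p$x0, p), dim(Is)), Is,
                       material_gamma(m), p$sigma_r2, g)
range(hy$sigma_o2)          # 2.4e-05 ... 5.202856 um^2, linear in thickness
```

The first two numbers say: at this system's working point a 2 µm refraction
shift costs ~2.4% of the peak intensity, the same drop a purely scattering
sample with σo² ≈ 4 µm² (≈147 µrad²) would cause — which is why refraction
can be neglected at the peak while scattering remains measurable.

A full simulate → retrieve → reconstruct chain is available through run
configs (`cmd_simulate()`, `cmd_retrieve()`, `cmd_recon()`) or the CLI
wrapper:

```sh
Rscript inst/cli/eidark simulate --config cfg.json --out-dir out/
Rscript inst/cli/eidark retrieve --config cfg.json --stack out/frames --out-dir out/
Rscript inst/cli/eidark recon    --config cfg.json --stack out/frames --out-dir out/
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the installed package, the worked-example quantities above:
the percentage peak-intensity drop for a pure 2 µm shift (t1), the
equivalent scattering variance in µm² (t2), and the thick-edge attenuation
percentage of the foamed-polystyrene wedge derived from its imaginary
refractive-index part at the Mo Kα design energy (t5), and writes them to
the given JSON path.

## Package layout

* `R/geometry.R` — system geometry, magnification, length²/angle² conversions
* `R/forward.R` — illumination-curve model, frame simulation, sensitivity curves
* `R/phantoms.R` — materials (δ, β, ε), wedges, cylinders, line integrals
* `R/retrieval.R` — Gaussian fitting, conventional / single-shot / hybrid retrieval, γ estimation
* `R/tomography.R` — dither interleaving, sinograms, FBP, cupping metric
* `R/io.R`, `R/pipeline.R` — text-based artifact formats, run configs, pipeline verbs
* `vignettes/hybrid-darkfield.Rmd` — model assumptions, parameter choices, limitations
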