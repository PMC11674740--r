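{
  "polystyrene": {
    "comment": "foamed polystyrene wedge; delta/beta at the Mo K-alpha design energy; eps is a synthetic fixture chosen so the 16 mm thick edge scatters a few tens of um^2",
    "delta": 1.37e-08,
    "beta": 5.35e-12,
    "energy_kev": 17.48,
    "eps_urad2_per_m": 70000
  },
  "paper": {
    "comment": "paper wedge; delta/beta at the Mo K-alpha design energy; eps derived from the measured attenuation-to-scattering ratio gamma = 551 mrad^-2",
    "delta": 5.52e-07,
    "beta": 3.59e-10,
    "energy_kev": 17.48,
    "gamma_mrad2inv": 551
  },
  "benchmark_scatterer": {
    "comment": "synthetic material for homogeneous-cylinder cupping benchmarks: weakly attenuating (mu = 2.6 /m), gamma = 200 mrad^-2, no refraction",
    "delta": 0,
    "mu_per_m": 2.6,
    "energy_kev": 17.48,
    "gamma_mrad2inv": 200
  }
}
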