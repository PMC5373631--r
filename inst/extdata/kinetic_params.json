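{
  "_comment": "Kinetic parameter sets for the three-state actin model, keyed by the simulated scenario. Rates are per arbitrary time unit; concentrations non-dimensional. k is printed; alpha_f/alpha_b variants and the pool scalings are printed; the remaining rates are the package's calibrated baseline (see the methods vignette).",
  "baseline": {
    "alpha_f": 0.32, "gamma_f": 0.002, "beta_f": 0.06, "k": 0.22,
    "alpha_b": 0.03, "gamma_b": 0.0035, "beta_b": 0.01,
    "hill_h": 2, "total_actin": 0.4666, "phi_fp": 0.2
  },
  "fig2C": { "inherit": "baseline" },
  "fig2D": { "inherit": "baseline", "alpha_f": 0.1 },
  "fig2E": { "inherit": "baseline", "alpha_b": 0.05 },
  "fig2F": { "inherit": "baseline", "alpha_f": 0.1, "alpha_b": 0.05 },
  "fig3E": { "inherit": "baseline", "alpha_b": 0.05, "total_actin_scale": 0.7 },
  "fig3F": { "inherit": "baseline", "alpha_b": 0.05, "total_actin_scale": 1.15 },
  "S3":    { "inherit": "baseline", "alpha_b": 0.05 },
  "S4":    { "inherit": "baseline", "alpha_f": 0.1 }
}
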