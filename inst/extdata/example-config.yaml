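# Example project configuration for the five-setron assay.
seed: 42
output_dir: qams-out
reference: ondansetron
noise_sd: 0.02
baseline_drift: 0.0
response_rsd_pct: 0
concentrations:
  azasetron: 20
  granisetron: 20
  tropisetron: 20
  ondansetron: 20
  ramosetron: 10
thresholds:
  min_snr: 10
  rrt_tol_pct: 5
  raw_sim_min: 0.99
  deriv_sim_min: 0.90
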