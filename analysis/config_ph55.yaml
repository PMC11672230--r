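# Run configuration: saturated COE-3 layer at pH 5.5 (IS = 25 mM, 20 C).
# The simulated experiment is the synthetic twin of the three-contrast
# reflectivity measurement; seeds make every step reproducible.
output_dir: results/ph55
seed: 55
protein: COE-3
stack:
  ph_label: "5.5"
noise:
  relative_error_floor: 0.02
  background_level: 5.0e-7
instrument:
  scale: 1.0
  background: 0.0
  dq_over_q: 0.04
simulate:
  q_min: 0.008
  q_max: 0.25
  n_points: 80
  prefix: ph55
fit:
  n_slabs: auto
  max_slabs: 3
  threshold: 0.10
  n_starts: 16
bootstrap:
  n_resamples: 200
  method: points
md:
  layout: flat_on
  center_z: 27.5
  contact_cutoff: 5
  n_per_fragment: 1200
  bin_width: 2
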