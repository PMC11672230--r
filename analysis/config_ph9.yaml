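# Run configuration: COE-3 layer after the pH 5.5 -> 9 buffer exchange.
# The tilted pseudo-conformation mimics the Fab-anchored, Fc-elevated
# orientation inferred at pH 9.
output_dir: results/ph9
seed: 9
protein: COE-3
stack:
  ph_label: "9"
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
  prefix: ph9
fit:
  n_slabs: auto
  max_slabs: 3
  threshold: 0.10
  n_starts: 16
bootstrap:
  n_resamples: 200
  method: points
md:
  layout: tilted
  center_z: 31.6
  contact_cutoff: 5
  n_per_fragment: 1200
  bin_width: 2
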