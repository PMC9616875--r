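# Demo run: simulated organoid photoactivation experiment, end to end.
# Two conditions (illuminated + doxycycline vs doxycycline only), four
# replicate fields each, followed by background subtraction, leak-through
# correction, per-channel segmentation, gated particle quantification and
# the whole-curve permutation test; plus a skin z-stack depth profile.
seed: 1
output_dir: pacre_demo_run
write_stacks: false
organoid:
  n_fields: 4
  conditions: [light_dox, dox_only]
  n_timepoints: 6
  frame_interval_h: 8
  field_size_um: [480, 480]
  n_cells: 200
recombination:
  background_hazard_per_h: 0.005
  light_hazard_multiplier: 20
  photoswitch_fraction: 0.8
  red_decay_halflife_h: 1
  illumination_time_h: 0
optics:
  leakthrough_lf_true: 0.15
  background_offset: 10
  gaussian_sd: 2
  poisson_gain: 0.5
  z_attenuation_per_um: 0.01
segmentation:
  method: otsu
  gates: organoid
leakthrough:
  source: nGFP
  target: cYFP
stats:
  n_perm: 1000
  groups: [light_dox, dox_only]
  alpha: 0.05
skin:
  enabled: true
  n_timepoints: 5
  frame_interval_h: 48
  relocation_day: 5
  n_z: 10
  field_size_um: [64, 64]
  n_cells: 12
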