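# Summary constants of the published BRD9 simulation campaign, used when
# re-deriving table arithmetic without re-running the 100-ns trajectories.
apo_filter:
  threshold_angstrom: 2.5
  filtered_total: 192     # snapshot-crystal pairs passing the 2.5 A filter
  n_frames: 3000          # apo snapshots tested per crystal
apo_reference:
  rmsd_mean_angstrom: 2.79
  rg_width_angstrom: 0.72
temperature_kelvin: 298.15
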