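# Pipeline configuration: canonical single-jet phantom study.
seed: 101
offset_mm: 15
roi_frac: 0.1
core_threshold: 0.5
phantom:
  regurgitant_volume: 11   # mL over systole
  forward_volume: 78       # mL diastolic inflow
  circularity: 0.61        # programmed b/a of the jet core
  sweep_deg: [50, 86]      # jet-annulus angle sweep, 2-chamber view
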