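# Demo: per-cell FBA accumulation with vehicle-control background
# subtraction and the standard outlier ruleset.
assay: accumulation
seed: 4
simulate:
  field_width_px: 300
  field_height_px: 300
segmentation:
  mode: spot
  sigma_um: 2
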