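# Demo: single-cell cytotoxicity time-lapse on a small synthetic field.
# Segmentation runs on frame 1, ROIs are frozen, death is called from the
# PI trace (>100 a.u. above background), and cells are stratified into
# FBA-accumulation tertiles.
assay: timelapse
seed: 9
simulate:
  field_width_px: 260
  field_height_px: 260
  n_frames: 19            # 3 h at 10-min intervals, demo scale
  death_base_logodds: -3.3
  debris_rate_per_mm2: 0
segmentation:
  mode: spot
  sigma_um: 2
death_threshold_au: 100
pi_roi: cytosol
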