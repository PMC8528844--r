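out_dir: ki67window_run
seeds:
  slides: 101
  patches: 11
  classifier: 2
  trial: 31
  expression: 41
slide_panel:
  n_rois: 20
  positive_fraction_range:
  - 0.05
  - 0.6
  n_train_slides: 4
  per_slide: 400
  split_fraction: 0.8
scoring:
  detection_threshold: 0.25
  min_separation_px: 15.0
  dab_threshold: 0.2
  brightness_threshold: 0.8
  min_cells: 30
trial:
  alpha: 0.05
  e2_limit: 44.0
expression:
  k: 10
  center_batches: no
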