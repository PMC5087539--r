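# Example pipeline configuration; omitted keys fall back to package defaults.
seed: 1
pantex:
  levels: 256
  window_size: 7
  threshold: 1.45
morphology:
  directions: [0, 45, 90, 135]
  s_min: 2
  s_max: 65
  delta_s: 7
rules:
  index_kind: MBI
  index_min: 6
  brightness_min: 136
  ndvi_max: 0.1
  lw_ratio_min: 1.5
  lw_ratio_max: 4.5
  rect_fit_min: 0.6
  shape_index_max: 2.6
  fill_box: 5
  poi_radius_m: 50
shadow:
  method: MSI        # or CIIT
  min_area_m2: 50
  max_lw_ratio: 8
  ndvi_max: 0.1
  ndwi_max: 0.1
  aggregator: median
height:
  idw_power: 2
  max_distance_m: 100
  default_height_m: 10
population:
  round_floors: false
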