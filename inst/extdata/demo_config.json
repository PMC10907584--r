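{
  "seed": 20170918,
  "out_dir": "demo_out",
  "phantom": {
    "grid_shape": [48, 48, 48],
    "voxel_size_mm": [1, 1, 1],
    "wm_intensity": 100,
    "noise_sd": 0,
    "tubes": [
      {"endpoint_a_mm": [10, 12, 12], "endpoint_b_mm": [24, 12, 12],
       "radius_mm": 1.0, "contrast_fraction": 0.35},
      {"endpoint_a_mm": [34, 10, 30], "endpoint_b_mm": [34, 24, 30],
       "radius_mm": 1.5, "contrast_fraction": 0.30},
      {"endpoint_a_mm": [14, 34, 18], "endpoint_b_mm": [14, 34, 34],
       "radius_mm": 2.0, "contrast_fraction": 0.30},
      {"endpoint_a_mm": [30, 36, 8], "endpoint_b_mm": [42, 36, 8],
       "radius_mm": 1.0, "contrast_fraction": 0.40}
    ]
  },
  "detection": {
    "diff_threshold": 0.15,
    "percentile_cut": 5,
    "neighborhood_radius_mm": 5,
    "erosion_voxels": 1,
    "min_cluster_volume_mm3": 1.0,
    "connectivity": 26
  },
  "dwi": {
    "grid_shape": [24, 24, 24],
    "voxel_size_mm": [2, 2, 2],
    "tensor": [[1.2e-3, 0, 0], [0, 0.7e-3, 0], [0, 0, 0.9e-3]],
    "s0": 1000,
    "noise_sd": 0
  },
  "alps": {
    "proj_center": [29, -4, 10],
    "assoc_center": [41, -4, 10],
    "diameter_mm": 4
  },
  "cohort": {},
  "model": {"grouping": "sans", "reference": "BDC-7"}
}
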