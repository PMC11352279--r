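# Demo pipeline configuration: two phantom conditions at coarse voxels.
# Run with:
#   inst/exec/granulemetrics --config demo_config.yaml --seed 1 --out out/
conditions:
  untreated:
    phantom:
      n_cells: 4
      voxel_size_nm: 8
      cell_length_range_nm: [1800, 3400]
      cell_radius_nm: 450
  cm_treated:
    phantom:
      n_cells: 4
      voxel_size_nm: 8
      cell_length_range_nm: [1800, 3400]
      cell_radius_nm: 450
coloc_threshold_nm: 25
phb_density_g_cm3: 1.170
seed: 1
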