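{
  "strains": [
    {
      "strain": "Ch1",
      "role": "defector",
      "marker": "rifampicin"
    },
    {
      "strain": "WT",
      "role": "cooperator",
      "marker": null
    }
  ],
  "pairs": [
    {
      "pair_id": "Ch1:WT",
      "strain_a": "Ch1",
      "strain_b": "WT",
      "ratio_a": 1,
      "ratio_b": 9,
      "subtraction_strain": "WT",
      "analysis": "W"
    }
  ],
  "density_cells_per_ml": 5000000000,
  "spot_volume_ml": 0.1
}
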