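{
  "n_units": 60,
  "n_designated": 26,
  "n_micro_regions": 3,
  "hub_unit": "U01",
  "hub_bed_share": 0.75,
  "hub_pop_share": 0.52,
  "population_range": [2000, 120000],
  "birth_rate": 0.015,
  "episodes_per_birth": 1.1,
  "attraction_exponent": 1,
  "decay_scale_km": 15,
  "local_preference": 30,
  "hub_preference": 4,
  "beds_per_1000": 2.46,
  "bed_unit_fraction": 0.5,
  "bounding_box": {
    "lat_min": -21.95,
    "lat_max": -20.45,
    "lon_min": -48.65,
    "lon_max": -47.05
  },
  "year": 2012,
  "seed": 1
}
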