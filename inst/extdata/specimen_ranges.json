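{
  "version": "1.0",
  "comment": "Default per-species morphology parameter table for the synthetic specimen generator. Continuous/integer characters carry printed min-max ranges (sampled uniformly; no distribution is published); categorical characters are fixed to each species' reported states. Tooth counts are intersected with the type definitions where the reported range extends outside them.",
  "species": [
    {
      "name": "T. shetlandica",
      "body_length_mm": [5.0, 16.0], "complete": true,
      "abdominal_chaetigers": [25, 34], "lamellae": [22, 26],
      "filament_um": [175.0, 225.0], "depth_m": [25, 375],
      "fusion_fraction": [0.16, 0.28], "reduced_lobes": false,
      "fifth_lobe_present": false,
      "thoracic_uncinus": {"rostrum": 2.0, "capitium": 1.0,
        "teeth": [5, 7], "size": "small", "rows": 2},
      "abdominal_uncinus": {"rostrum": 1.0, "capitium": 0.9,
        "teeth": [4, 5], "size": "mid", "rows": 1},
      "mg_pattern": "1", "mg_j_segments": [],
      "white_venter": [], "ciliated_papilla": false,
      "ciliary_tufts": false, "notochaetae_tc1": "similar",
      "glandular_tc3": "absent", "geniculate_chaetigers": [6]
    },
    {
      "name": "T. lavesquei",
      "body_length_mm": [5.0, 35.0], "complete": true,
      "abdominal_chaetigers": [30, 31], "lamellae": [17, 42],
      "filament_um": [125.0, 250.0], "depth_m": [115, 534],
      "fusion_fraction": [0.4, 0.6], "reduced_lobes": false,
      "fifth_lobe_present": true,
      "thoracic_uncinus": {"rostrum": 2.0, "capitium": 1.0,
        "teeth": [4, 5], "size": "mid", "rows": 1},
      "abdominal_uncinus": {"rostrum": 1.0, "capitium": 0.9,
        "teeth": [4, 5], "size": "mid", "rows": 1},
      "mg_pattern": "9", "mg_j_segments": [3, 4, 5],
      "white_venter": [], "ciliated_papilla": false,
      "ciliary_tufts": false, "notochaetae_tc1": "similar",
      "glandular_tc3": "J_shaped", "geniculate_chaetigers": [6]
    },
    {
      "name": "T. atlantis",
      "body_length_mm": [10.0, 16.0], "complete": true,
      "abdominal_chaetigers": [23, 28], "lamellae": [10, 11],
      "filament_um": [150.0, 175.0], "depth_m": [219, 2750],
      "fusion_fraction": [0.05, 0.25], "reduced_lobes": false,
      "fifth_lobe_present": false,
      "thoracic_uncinus": {"rostrum": 2.0, "capitium": 1.0,
        "teeth": [4, 4], "size": "mid", "rows": 1},
      "abdominal_uncinus": {"rostrum": 1.0, "capitium": 0.9,
        "teeth": [4, 5], "size": "mid", "rows": 1},
      "mg_pattern": "9", "mg_j_segments": [3, 4, 5],
      "white_venter": [], "ciliated_papilla": false,
      "ciliary_tufts": false, "notochaetae_tc1": "similar",
      "glandular_tc3": "absent", "geniculate_chaetigers": [6]
    },
    {
      "name": "T. irinae",
      "body_length_mm": [10.0, 17.0], "complete": false,
      "abdominal_chaetigers": [18, 20], "lamellae": [7, 7],
      "filament_um": [75.0, 75.0], "depth_m": [4038, 4380],
      "fusion_fraction": [0.0, 0.1], "reduced_lobes": true,
      "fifth_lobe_present": true,
      "thoracic_uncinus": {"rostrum": 2.0, "capitium": 1.0,
        "teeth": [4, 5], "size": "mid", "rows": 1},
      "abdominal_uncinus": {"rostrum": 1.0, "capitium": 0.9,
        "teeth": [4, 5], "size": "mid", "rows": 1},
      "mg_pattern": "1", "mg_j_segments": [],
      "white_venter": [], "ciliated_papilla": false,
      "ciliary_tufts": false, "notochaetae_tc1": "similar",
      "glandular_tc3": "absent", "geniculate_chaetigers": [6]
    },
    {
      "name": "T. williamsae",
      "body_length_mm": [9.0, 34.0], "complete": true,
      "abdominal_chaetigers": [38, 44], "lamellae": [16, 18],
      "filament_um": [50.0, 50.0], "depth_m": [178, 612],
      "fusion_fraction": [0.4, 0.6], "reduced_lobes": false,
      "fifth_lobe_present": true,
      "thoracic_uncinus": {"rostrum": 2.0, "capitium": 1.0,
        "teeth": [2, 3], "size": "large", "rows": 2},
      "abdominal_uncinus": {"rostrum": 1.0, "capitium": 0.7,
        "teeth": [3, 5], "size": "large", "rows": 2},
      "mg_pattern": "2", "mg_j_segments": [],
      "white_venter": [1, 2, 3, 4], "ciliated_papilla": true,
      "ciliary_tufts": true, "notochaetae_tc1": "similar",
      "glandular_tc3": "J_shaped", "geniculate_chaetigers": [6]
    },
    {
      "name": "T. gracilis",
      "body_length_mm": [5.0, 29.0], "complete": true,
      "abdominal_chaetigers": [34, 41], "lamellae": [23, 32],
      "filament_um": [125.0, 175.0], "depth_m": [237, 1268],
      "fusion_fraction": [0.4, 0.6], "reduced_lobes": false,
      "fifth_lobe_present": true,
      "thoracic_uncinus": {"rostrum": 2.0, "capitium": 1.0,
        "teeth": [2, 3], "size": "large", "rows": 2},
      "abdominal_uncinus": {"rostrum": 1.0, "capitium": 0.7,
        "teeth": [3, 5], "size": "large", "rows": 2},
      "mg_pattern": "2", "mg_j_segments": [],
      "white_venter": [4], "ciliated_papilla": true,
      "ciliary_tufts": true, "notochaetae_tc1": "similar",
      "glandular_tc3": "J_shaped", "geniculate_chaetigers": [6]
    }
  ]
}
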