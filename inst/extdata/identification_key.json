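{
  "version": "1.0",
  "comment": "Dichotomous key to NE Atlantic species of the genus, 18 couplets. Predicates operate on derived specimen features; couplet 18 separates on bathymetry only, so its terminals are non-morphological.",
  "couplets": [
    {"number": 1, "leads": [
      {"predicates": [{"field": "white_venter_present", "op": "is_true"}],
       "couplet": 2},
      {"predicates": [{"field": "white_venter_present", "op": "is_false"}],
       "couplet": 4}
    ]},
    {"number": 2, "leads": [
      {"predicates": [
        {"field": "size_class", "op": "in", "value": ["medium", "large"]},
        {"field": "fifth_lobe_present", "op": "is_true"},
        {"field": "notochaetae_tc1", "op": "eq", "value": "similar"},
        {"field": "thoracic_uncini_type", "op": "eq", "value": "1"}],
       "couplet": 3},
      {"predicates": [
        {"field": "size_class", "op": "eq", "value": "small"},
        {"field": "fifth_lobe_present", "op": "is_false"},
        {"field": "notochaetae_tc1", "op": "in", "value": ["absent", "shorter"]},
        {"field": "thoracic_uncini_type", "op": "eq", "value": "3"}],
       "taxa": ["T. ceneresi"]}
    ]},
    {"number": 3, "leads": [
      {"predicates": [{"field": "white_venter", "op": "eq", "value": "TC1-4"}],
       "taxa": ["T. williamsae"]},
      {"predicates": [{"field": "white_venter", "op": "eq", "value": "TC4"}],
       "taxa": ["T. gracilis"]}
    ]},
    {"number": 4, "leads": [
      {"predicates": [{"field": "branchiae_type", "op": "eq", "value": "4"}],
       "taxa": ["T. irinae"]},
      {"predicates": [{"field": "branchiae_type", "op": "ne", "value": "4"}],
       "couplet": 5}
    ]},
    {"number": 5, "leads": [
      {"predicates": [
        {"field": "branchiae_type", "op": "in", "value": ["2", "3"]},
        {"field": "size_class", "op": "in", "value": ["small", "medium"]}],
       "couplet": 6},
      {"predicates": [
        {"field": "branchiae_type", "op": "eq", "value": "1"},
        {"field": "size_class", "op": "eq", "value": "large"}],
       "couplet": 9}
    ]},
    {"number": 6, "leads": [
      {"predicates": [{"field": "thoracic_uncini_type", "op": "eq", "value": "4"}],
       "taxa": ["T. shetlandica"]},
      {"predicates": [{"field": "thoracic_uncini_type", "op": "eq", "value": "3"}],
       "couplet": 7}
    ]},
    {"number": 7, "leads": [
      {"predicates": [
        {"field": "branchiae_type", "op": "eq", "value": "2"},
        {"field": "size_class", "op": "in", "value": ["medium", "large"]}],
       "taxa": ["T. lavesquei"]},
      {"predicates": [
        {"field": "branchiae_type", "op": "eq", "value": "3"},
        {"field": "size_class", "op": "eq", "value": "small"}],
       "couplet": 8}
    ]},
    {"number": 8, "leads": [
      {"predicates": [
        {"field": "glandular_tc3_present", "op": "is_true"},
        {"field": "notochaetae_tc1", "op": "eq", "value": "longer"}],
       "taxa": ["T. parapari"]},
      {"predicates": [
        {"field": "glandular_tc3_present", "op": "is_false"},
        {"field": "notochaetae_tc1", "op": "eq", "value": "similar"}],
       "taxa": ["T. atlantis"]}
    ]},
    {"number": 9, "leads": [
      {"predicates": [{"field": "geniculate_tc5", "op": "is_true"}],
       "taxa": ["T. bigeniculatus"]},
      {"predicates": [{"field": "geniculate_tc5", "op": "is_false"}],
       "couplet": 10}
    ]},
    {"number": 10, "leads": [
      {"predicates": [{"field": "papillae_on_lamellae", "op": "is_false"}],
       "couplet": 11},
      {"predicates": [{"field": "papillae_on_lamellae", "op": "is_true"}],
       "couplet": 13}
    ]},
    {"number": 11, "leads": [
      {"predicates": [{"field": "branchiae_type", "op": "eq", "value": "2"}],
       "taxa": ["T. gralli"]},
      {"predicates": [{"field": "branchiae_type", "op": "eq", "value": "1"}],
       "couplet": 12}
    ]},
    {"number": 12, "leads": [
      {"predicates": [{"field": "abdominal_cr_ratio", "op": "le", "value": 0.8}],
       "taxa": ["T. stroemii"]},
      {"predicates": [{"field": "abdominal_cr_ratio", "op": "gt", "value": 0.8}],
       "taxa": ["T. kongsrudi", "T. bakkeni"]}
    ]},
    {"number": 13, "leads": [
      {"predicates": [{"field": "glandular_tc3", "op": "in", "value": ["round", "oval"]}],
       "couplet": 14},
      {"predicates": [{"field": "glandular_tc3", "op": "in", "value": ["J_shaped", "absent"]}],
       "couplet": 15}
    ]},
    {"number": 14, "leads": [
      {"predicates": [{"field": "glandular_tc3_mg_stain", "op": "eq", "value": "white"}],
       "taxa": ["T. lilasae"]},
      {"predicates": [{"field": "glandular_tc3_mg_stain", "op": "eq", "value": "blue"}],
       "taxa": ["T. bonifi"]}
    ]},
    {"number": 15, "leads": [
      {"predicates": [{"field": "ciliary_tufts", "op": "is_true"}],
       "taxa": ["T. gentili"]},
      {"predicates": [{"field": "ciliary_tufts", "op": "is_false"}],
       "couplet": 16}
    ]},
    {"number": 16, "leads": [
      {"predicates": [{"field": "upper_lip_elongated", "op": "is_true"}],
       "taxa": ["T. resomari"]},
      {"predicates": [{"field": "upper_lip_elongated", "op": "is_false"}],
       "couplet": 17}
    ]},
    {"number": 17, "leads": [
      {"predicates": [{"field": "thoracic_uncini_type", "op": "eq", "value": "1"}],
       "taxa": ["T. ronningae"]},
      {"predicates": [{"field": "thoracic_uncini_type", "op": "eq", "value": "3"}],
       "couplet": 18}
    ]},
    {"number": 18, "leads": [
      {"predicates": [{"field": "depth_m", "op": "gt", "value": 200}],
       "taxa": ["T. norvegica"]},
      {"predicates": [{"field": "depth_m", "op": "le", "value": 200}],
       "taxa": ["T. europaea", "T. scotica"]}
    ]}
  ]
}
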