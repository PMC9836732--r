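{
  "version": "1.0",
  "comment": "Discriminating characters of the six focal NE Atlantic species. The white ventral colouration character is an augmentation from the species remarks: without it the two colouration-bearing species are separated only by distribution trends.",
  "taxa": ["T. shetlandica", "T. lavesquei", "T. atlantis",
           "T. irinae", "T. williamsae", "T. gracilis"],
  "characters": [
    {"name": "branchiae_type", "domain": ["1", "2", "3", "4"]},
    {"name": "papillae_on_lamellae", "domain": ["yes", "no"]},
    {"name": "ciliated_papilla", "domain": ["yes", "no"]},
    {"name": "geniculate_chaetae", "domain": ["TC6", "TC5-6", "other"]},
    {"name": "thoracic_uncini_type", "domain": ["1", "3", "4"]},
    {"name": "abdominal_uncini_type", "domain": ["1A", "2"]},
    {"name": "white_venter", "domain": ["none", "TC1-4", "TC4", "other"]}
  ],
  "states": [
    ["3", "no", "no", "TC6", "4", "2", "none"],
    ["2", "no", "no", "TC6", "3", "2", "none"],
    ["3", "no", "no", "TC6", "3", "2", "none"],
    ["4", "no", "no", "TC6", "3", "2", "none"],
    ["2", "no", "yes", "TC6", "1", "1A", "TC1-4"],
    ["2", "no", "yes", "TC6", "1", "1A", "TC4"]
  ]
}
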