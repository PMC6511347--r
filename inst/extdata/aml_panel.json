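{
  "detectors": ["FITC-A", "PE-A", "PerCP-Cy5.5-A", "PC7-A", "APC-A",
                "APC-AF750-A", "PB-A", "PO-A"],
  "tubes": [
    {"tube_id": 1,
     "markers": ["CD14", "CD11b", "HLA-DR", "CD13", "CD300e", "CD64", "CD4", "CD45"]},
    {"tube_id": 2,
     "markers": ["CD15", "CD123", "CD34", "CD13", "CD10", "CD16", "HLA-DR", "CD45"]},
    {"tube_id": 3,
     "markers": ["CD71", "CD117", "CD33", "CD56", "CD34", "CD38", "CD7", "CD45"]},
    {"tube_id": 4,
     "markers": ["cyFXIII-A", "cyMPO", "CD33", "CD2", "CD34", "CD117", "HLA-DR", "CD45"]}
  ]
}
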