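{
  "name": "MAPK",
  "comment": "Reduced MAPK signaling; complex nodes are the SOS, RAS, PKC, RAF, MEK and ERK paralog families; RAP1A and RAP1B kept as separate nodes. Edge topology reconstructed from the canonical KEGG diagram.",
  "nodes": [
    {"id": "SOS", "members": ["SOS1", "SOS2"], "latent": false},
    {"id": "NF1", "members": ["NF1"], "latent": false},
    {"id": "RASA2", "members": ["RASA2"], "latent": false},
    {"id": "RAS", "members": ["KRAS", "HRAS", "NRAS", "MRAS"], "latent": false},
    {"id": "RAPGEF2", "members": ["RAPGEF2"], "latent": false},
    {"id": "RAP1A", "members": ["RAP1A"], "latent": false},
    {"id": "RAP1B", "members": ["RAP1B"], "latent": false},
    {"id": "PRKC", "members": ["PRKCA", "PRKCB", "PRKCG"], "latent": false},
    {"id": "RAF", "members": ["RAF1", "BRAF"], "latent": false},
    {"id": "MAP2K", "members": ["MAP2K1", "MAP2K2"], "latent": false},
    {"id": "MAPK", "members": ["MAPK1", "MAPK3"], "latent": false}
  ],
  "edges": [
    ["SOS", "RAS"],
    ["NF1", "RAS"],
    ["RASA2", "RAS"],
    ["RAS", "RAF"],
    ["PRKC", "RAF"],
    ["RAPGEF2", "RAP1A"],
    ["RAPGEF2", "RAP1B"],
    ["RAP1A", "RAF"],
    ["RAP1B", "RAF"],
    ["RAF", "MAP2K"],
    ["MAP2K", "MAPK"]
  ]
}
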