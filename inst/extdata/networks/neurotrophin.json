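{
  "name": "Neurotrophin",
  "comment": "Reduced neurotrophin signaling (p75 branch); the JNK-family node keeps the symbols MAP8/MAP9/MAP10 exactly as printed in the source gene list (probable intent MAPK8/9/10). Edge topology reconstructed from the canonical KEGG diagram.",
  "nodes": [
    {"id": "NGFR", "members": ["NGFR"], "latent": false},
    {"id": "TRAF6", "members": ["TRAF6"], "latent": false},
    {"id": "RAC1", "members": ["RAC1"], "latent": false},
    {"id": "MAP3K1", "members": ["MAP3K1"], "latent": false},
    {"id": "MAP2K7", "members": ["MAP2K7"], "latent": false},
    {"id": "JNK", "members": ["MAP8", "MAP9", "MAP10"], "latent": false},
    {"id": "JUN", "members": ["JUN"], "latent": false},
    {"id": "TP53", "members": ["TP53"], "latent": false},
    {"id": "TP73", "members": ["TP73"], "latent": false}
  ],
  "edges": [
    ["NGFR", "TRAF6"],
    ["TRAF6", "RAC1"],
    ["RAC1", "MAP3K1"],
    ["MAP3K1", "MAP2K7"],
    ["MAP2K7", "JNK"],
    ["JNK", "JUN"],
    ["JNK", "TP53"],
    ["JNK", "TP73"]
  ]
}
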