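{
  "name": "Serine biosynthesis",
  "comment": "Reduced serine biosynthesis pathway; edge topology reconstructed from the canonical KEGG reaction chain.",
  "nodes": [
    {"id": "PHGDH", "members": ["PHGDH"], "latent": false},
    {"id": "PSAT1", "members": ["PSAT1"], "latent": false},
    {"id": "PSPH", "members": ["PSPH"], "latent": false},
    {"id": "SHMT1", "members": ["SHMT1"], "latent": false},
    {"id": "SHMT2", "members": ["SHMT2"], "latent": false}
  ],
  "edges": [
    ["PHGDH", "PSAT1"],
    ["PSAT1", "PSPH"],
    ["PSPH", "SHMT1"],
    ["PSPH", "SHMT2"]
  ]
}
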