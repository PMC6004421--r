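{
  "name": "Focal adhesion",
  "comment": "Reduced focal adhesion signaling; complex nodes are the CRK adaptors, class-I PI3K subunits, VAV, RAC, PAK paralog families and RAP1. Edge topology reconstructed from the canonical KEGG diagram.",
  "nodes": [
    {"id": "PTK2", "members": ["PTK2"], "latent": false},
    {"id": "BCAR1", "members": ["BCAR1"], "latent": false},
    {"id": "CRK", "members": ["CRK", "CRKL"], "latent": false},
    {"id": "DOCK1", "members": ["DOCK1"], "latent": false},
    {"id": "PI3K", "members": ["PIK3CA", "PIK3CB", "PIK3CD", "PIK3R1", "PIK3R2", "PIK3R3"], "latent": false},
    {"id": "PTEN", "members": ["PTEN"], "latent": false},
    {"id": "VAV", "members": ["VAV1", "VAV2", "VAV3"], "latent": false},
    {"id": "RAC", "members": ["RAC1", "RAC2", "RAC3"], "latent": false},
    {"id": "PAK", "members": ["PAK1", "PAK2", "PAK3", "PAK4", "PAK5", "PAK6"], "latent": false},
    {"id": "RAPGEF1", "members": ["RAPGEF1"], "latent": false},
    {"id": "RAP1", "members": ["RAP1A", "RAP1B"], "latent": false}
  ],
  "edges": [
    ["PTK2", "BCAR1"],
    ["PTK2", "PI3K"],
    ["PTEN", "PI3K"],
    ["BCAR1", "CRK"],
    ["CRK", "DOCK1"],
    ["CRK", "RAPGEF1"],
    ["RAPGEF1", "RAP1"],
    ["DOCK1", "RAC"],
    ["PI3K", "VAV"],
    ["VAV", "RAC"],
    ["RAC", "PAK"]
  ]
}
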