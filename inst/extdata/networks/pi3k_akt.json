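{
  "name": "PI3K-Akt",
  "comment": "Reduced PI3K-Akt signaling; complex nodes are the class-I PI3K subunit family and the TSC1-TSC2 complex. Edge topology reconstructed from the canonical KEGG diagram.",
  "nodes": [
    {"id": "IRS1", "members": ["IRS1"], "latent": false},
    {"id": "PTK2", "members": ["PTK2"], "latent": false},
    {"id": "PI3K", "members": ["PIK3CA", "PIK3CB", "PIK3CD", "PIK3R1", "PIK3R2", "PIK3R3"], "latent": false},
    {"id": "PDPK1", "members": ["PDPK1"], "latent": false},
    {"id": "PTEN", "members": ["PTEN"], "latent": false},
    {"id": "AKT3", "members": ["AKT3"], "latent": false},
    {"id": "CRTC2", "members": ["nCRTC2"], "latent": false},
    {"id": "FOXO3", "members": ["FOXO3"], "latent": false},
    {"id": "BAD", "members": ["BAD"], "latent": false},
    {"id": "GSK3B", "members": ["GSK3B"], "latent": false},
    {"id": "TSC", "members": ["TSC1", "TSC2"], "latent": false}
  ],
  "edges": [
    ["IRS1", "PI3K"],
    ["PTK2", "PI3K"],
    ["PI3K", "PDPK1"],
    ["PI3K", "AKT3"],
    ["PTEN", "AKT3"],
    ["PDPK1", "AKT3"],
    ["AKT3", "TSC"],
    ["AKT3", "FOXO3"],
    ["AKT3", "BAD"],
    ["AKT3", "GSK3B"],
    ["AKT3", "CRTC2"]
  ]
}
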