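[
  {
    "id": "cenpc_motif_vertebrate",
    "pattern": "NVRRTKRXRLKPLEYWRGERVBY",
    "note": "23-residue vertebrate CENP-C motif consensus (25-species alignment)"
  },
  {
    "id": "cenpc_motif_identities",
    "pattern": "RxxRxxxxPLxYWxGERxxY",
    "note": "identity positions within the vertebrate CENP-C motif"
  },
  {
    "id": "cenpc_motif_core",
    "pattern": "RxxxxPxxYW",
    "note": "core CENP-C motif implicated in nucleosome binding"
  },
  {
    "id": "central_region_consensus",
    "pattern": "RxSxxPSxWW",
    "note": "CENP-C central-region consensus"
  },
  {
    "id": "central_region_core",
    "pattern": "RxxxxPxxWW",
    "note": "functionally important core of the central-region consensus"
  }
]
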