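{
  "name": "XY univalent",
  "mII_rule": "regular_sisters",
  "chromosomes": [
    {
      "name": "XY",
      "dna_content": [1, 1],
      "conjunction": "univalent_pair",
      "probe": ["red", "green"]
    },
    {
      "name": "chr2",
      "dna_content": [1, 1],
      "conjunction": "bivalent",
      "probe": ["none", "none"]
    },
    {
      "name": "chr3",
      "dna_content": [1, 1],
      "conjunction": "bivalent",
      "probe": ["none", "none"]
    },
    {
      "name": "chr4",
      "dna_content": [0.2, 0.2],
      "conjunction": "bivalent",
      "probe": ["none", "none"]
    }
  ]
}
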