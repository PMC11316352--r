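{
  "adaptation_genes": ["cas1", "cas2"],
  "interference_genes": {
    "I-E": ["cas3", "cse1", "cse2", "cas7", "cas5", "cas6e"],
    "I-G": ["cas3", "csb2", "cas7", "cas5"],
    "III-B": ["cas10", "cmr1", "cmr3", "cmr4", "cmr5", "cmr6"]
  }
}
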