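{
  "groups": {
    "nitrogen": ["narB", "nirA", "nrtA", "nrtB", "nrtC", "amt", "urtA"],
    "sulfur": ["cysD", "cysN", "cysC", "cysH", "sir"],
    "ros": ["katE", "sod1"],
    "pigment": ["cpeA", "cpeB"],
    "motility_chemotaxis": ["pilA", "cheB", "cheR"],
    "cold": ["treS", "otsA", "otsB"],
    "humic": ["mlhB"]
  },
  "ecotype_markers": {
    "SC5.3": ["cpeA", "cpeB"],
    "LN": ["cpeA", "cpeB"],
    "LNLT": ["treS", "otsA", "otsB", "cpeA", "cpeB"],
    "HN": ["cheB", "cheR", "pilA"],
    "LP": ["mlhB"]
  },
  "pigment": {
    "SC5.3": "red",
    "LN": "red",
    "LNLT": "red",
    "HN": "green",
    "LP": "green"
  },
  "background_rate": 0.05,
  "background_exempt": ["cpeA", "cpeB"]
}
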