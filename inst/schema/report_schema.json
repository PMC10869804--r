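{
  "title": "dimerlab pipeline report",
  "type": "object",
  "required": ["provenance"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["package", "version", "seed", "timestamp"]
    },
    "surface": {"type": "object"},
    "ensemble": {"type": "object"},
    "geometry": {"type": "object"},
    "csp": {"type": "object"},
    "fit": {"type": "object"},
    "conserve": {"type": "object"}
  }
}
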