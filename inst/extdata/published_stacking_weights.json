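{
  "crg": 0.68,
  "mrna4": 0.25,
  "gene24": 0.07
}
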