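{
  "name": "empty",
  "version": "1",
  "provenance_note": "starting point for building a vocabulary from scratch",
  "features": {}
}
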