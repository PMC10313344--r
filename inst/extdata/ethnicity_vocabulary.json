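{
  "name": "ethnicity-demo",
  "version": "1",
  "provenance_note": "worked demographic example: one feature with synonym and three instances",
  "features": {
    "ethnicity": {
      "synonyms": ["race"],
      "instances": {
        "Black": ["B", "African-American"],
        "White": ["Caucasian", "C"],
        "Inuit": []
      }
    }
  }
}
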