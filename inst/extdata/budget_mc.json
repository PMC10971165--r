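{
  "description": "k=1 relative uncertainty components (percent) of the Monte Carlo simulation of the full-scatter factor F.",
  "components": [
    { "name": "(sw,air*p*Wair)_Co-60 from TRS-398", "kind": "B", "value": 0.8 },
    { "name": "Clinic Monte Carlo physics", "kind": "B", "value": 1.6 },
    { "name": "Phantom composition and density", "kind": "B", "value": 0.6 },
    { "name": "Materials' cross-sections", "kind": "B", "value": 0.1 }
  ]
}
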