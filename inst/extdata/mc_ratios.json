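{
  "description": "Monte Carlo full-scatter vs PMMA mini-phantom dose ratios for a microSelectron HDR v2 Ir-192 source at the 4 cm calibration distance, with k=1 relative uncertainties in percent, and their experimental validation ratios. Transcribed fixture; not recomputed by this package.",
  "version": 1,
  "sw_air_p_u_rel_pct": 0.8,
  "ratios": {
    "dpol_full_over_dpol_pmma": { "value": 1.075, "u_rel_pct": 2.4 },
    "dw_full_over_dw_pmma": { "value": 1.096, "u_rel_pct": 2.4 },
    "dair_full_over_dair_pmma": { "value": 1.086, "u_rel_pct": 2.4 },
    "dw_full_over_dair_pmma_ir192": {
      "value": 1.226536,
      "u_rel_pct": 2.4,
      "derived": true,
      "note": "back-derived as F = 1.103 times the TRS-398 constant 1.112; the absolute ratio is not a primary published quantity"
    }
  },
  "experimental": {
    "dpol_full_over_dpol_pmma": { "value": 1.084, "u_rel_pct": 2.1 },
    "dair_full_over_dair_pmma": { "value": 1.106, "u_rel_pct": 2.9 }
  }
}
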