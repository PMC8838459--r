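{
  "_comment": "Synthetic nested-band error-grid partition for MAP. A pair falls in the first region whose absolute (mmHg) OR relative (%) error bound it satisfies; the last region is unbounded. Package-defined stand-in, user-replaceable.",
  "region": ["A", "B", "C", "D", "E"],
  "abs_mmHg": [5, 10, 15, 25, "Inf"],
  "rel_pct": [10, 20, 30, 50, "Inf"]
}
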