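{
  "name": "TO-215",
  "genes_file": "to_genes.txt",
  "matched_normal": false,
  "af_floor": 0.02,
  "min_alt_reads": 4,
  "depth_rule": {"type": "fixed", "value": 0},
  "reporting_cap": 14,
  "mean_depth": 3000
}
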