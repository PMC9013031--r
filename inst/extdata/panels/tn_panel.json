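{
  "name": "TN-114",
  "genes_file": "tn_genes.txt",
  "matched_normal": true,
  "af_floor": 0.02,
  "min_alt_reads": 4,
  "depth_rule": {"type": "cellularity_tiered", "high": 200, "mid": 250, "low": 500, "lower": 0.2, "upper": 0.5},
  "reporting_cap": null,
  "mean_depth": 600
}
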