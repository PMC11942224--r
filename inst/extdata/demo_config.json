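{
  "seed": 42,
  "output_dir": "broadmark_demo_out",
  "simulate": {
    "n_genes": 300,
    "n_chroms": 2,
    "chrom_length": 5000000,
    "fractions": {
      "all": 0.40,
      "normal_only": 0.10,
      "cancer_common": 0.05,
      "one_cancer": 0.05
    },
    "narrow_frac": 0.5,
    "lambda0": 2,
    "enrichment": 8,
    "depth": 1,
    "samples": [
      { "sample_id": "N1", "group": "normal" },
      { "sample_id": "C1", "group": "cancer" },
      { "sample_id": "C2", "group": "cancer" },
      { "sample_id": "C3", "group": "cancer" },
      { "sample_id": "REF1", "group": "reference_normal" }
    ]
  },
  "calling": {
    "bin_size": 50,
    "q_strong": 0.05,
    "q_weak": 0.1,
    "min_peak_len": 150,
    "broad_gap": 1000
  },
  "window_up": 1000,
  "window_down": 1000,
  "broad_fraction": 0.05,
  "relaxed_q": 0.2,
  "profile_flank": 5000,
  "write_tracks": false
}
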