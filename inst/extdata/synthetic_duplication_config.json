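{
  "alignment": "synthetic_duplication.fasta",
  "tree": "synthetic_duplication.nwk",
  "labels": "synthetic_duplication_labels.tsv",
  "groups": {
    "g1": ["g1_sp1", "g1_sp2", "g1_sp3", "g1_sp4", "g1_sp5", "g1_sp6", "g1_sp7"],
    "g5": ["g5_sp1", "g5_sp2", "g5_sp3", "g5_sp4", "g5_sp5", "g5_sp6"],
    "outgroup": "outgroup"
  },
  "branch_models": ["M0", "M2r", "M3r"],
  "branch_lrt_pairs": [
    ["M2r", "M0"],
    ["M3r", "M2r"]
  ],
  "site_models": ["M1", "M3"],
  "site_lrt_pairs": [
    ["M3", "M1"]
  ],
  "branch_site_foregrounds": {
    "g1": ["stem_g1", "g1"]
  },
  "calibration": {
    "T_calibration": 50,
    "dS_ortholog": 0.388,
    "dS_paralog": 0.592
  },
  "out_dir": "synthetic_run",
  "seed": 7
}
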