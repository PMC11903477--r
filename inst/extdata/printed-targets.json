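{
  "comment": "Published group-level targets: exact integer counts for the tap test and DESH sign per outcome group, 2-dp accuracy values for each prediction rule, and the reported Youden-optimal callosal angle cutoff.",
  "group_sizes": {"responders": 96, "non_responders": 70},
  "tap_positive": {"responders": 61, "non_responders": 28},
  "desh_positive": {"responders": 53, "non_responders": 8},
  "table4": {
    "tap": {"sensitivity": 0.64, "specificity": 0.60, "auc": 0.62},
    "desh": {"sensitivity": 0.55, "specificity": 0.89, "auc": 0.72},
    "ca": {"sensitivity": 0.45, "specificity": 0.74, "auc": 0.60},
    "tap_desh": {"sensitivity": 0.79, "specificity": 0.53, "auc": 0.66},
    "tap_ca": {"sensitivity": 0.85, "specificity": 0.51, "auc": 0.68},
    "majority": {"sensitivity": 0.77, "specificity": 0.67, "auc": 0.72}
  },
  "ca_cutoff": 68.7
}
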