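{
  "description": "Demographic summary of the four multi-site MRI cohorts (NIH, C-MIND, fCONN, IXI) pooled for lifespan tissue-template construction, after quality screening.",
  "initial_n": 2081,
  "datasets": [
    {"dataset": "NIH",   "n": 389, "males": 184, "females": 205, "n_3t": 0,   "n_15t": 389},
    {"dataset": "CMIND", "n": 211, "males": 93,  "females": 118, "n_3t": 211, "n_15t": 0},
    {"dataset": "fCONN", "n": 770, "males": 345, "females": 416, "n_3t": 754, "n_15t": 16},
    {"dataset": "IXI",   "n": 544, "males": 242, "females": 302, "n_3t": 366, "n_15t": 178}
  ]
}
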