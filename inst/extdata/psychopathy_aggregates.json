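{
  "description": "Published aggregate summaries from an extreme-groups psychopathy study of moral dilemma judgment: per-group mean (SD) action scores (0-6) for the four dilemma types, group sizes, and LSRP total summaries. Type order: proscriptive/greater, proscriptive/smaller, prescriptive/greater, prescriptive/smaller.",
  "items_per_type": 6,
  "type_order": [
    "proscriptive/greater",
    "proscriptive/smaller",
    "prescriptive/greater",
    "prescriptive/smaller"
  ],
  "groups": [
    {
      "label": "high",
      "n_subjects": 174,
      "mean_action": [3.00, 2.18, 3.91, 3.21],
      "sd_action": [1.31, 1.40, 1.46, 1.28],
      "lsrp_mean": 84.21,
      "lsrp_sd": 6.39
    },
    {
      "label": "low",
      "n_subjects": 188,
      "mean_action": [2.46, 1.56, 4.51, 3.60],
      "sd_action": [1.44, 1.28, 1.26, 1.40],
      "lsrp_mean": 47.44,
      "lsrp_sd": 6.28
    }
  ]
}
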