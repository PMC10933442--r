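{
  "comment": "Reference arousal-intensity level edges in volts; right-closed intervals (lower_edge, q1] -> level 1, (q1, q2] -> 2, (q2, q3] -> 3, (q3, upper_edge] -> 4. Cohort-specific; the default scoring mode refits quartiles from the data at hand.",
  "lower_edge": -0.001,
  "q1": 9.3e-5,
  "q2": 1.64e-4,
  "q3": 4.04e-4,
  "upper_edge": 6.03e-3
}
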