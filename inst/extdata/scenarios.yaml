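# The eight canonical MCAR/MAR attrition scenarios.
# p1/p2: per-time-point event probability in categories C1/C2;
# r1/r2: drop-out probability after each time point in C1/C2.
- scenario_id: "1"
  p1: 0.1
  p2: 0.1
  r1: 0.1
  r2: 0.1
- scenario_id: "2"
  p1: 0.1
  p2: 0.3
  r1: 0.1
  r2: 0.1
- scenario_id: "3"
  p1: 0.1
  p2: 0.6
  r1: 0.1
  r2: 0.1
- scenario_id: "4"
  p1: 0.1
  p2: 0.1
  r1: 0.1
  r2: 0.6
- scenario_id: "5"
  p1: 0.1
  p2: 0.3
  r1: 0.1
  r2: 0.6
- scenario_id: "6"
  p1: 0.1
  p2: 0.6
  r1: 0.1
  r2: 0.6
- scenario_id: "7"
  p1: 0.1
  p2: 0.3
  r1: 0.6
  r2: 0.1
- scenario_id: "8"
  p1: 0.1
  p2: 0.6
  r1: 0.6
  r2: 0.1
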