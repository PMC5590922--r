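# Factor roles for the Hong Kong Hospital Authority cluster benchmark.
# Weights are omitted: the equal split within each normalization group is
# assigned at load time.
factors:
  DI1: {role: DI, unit: "1 person (FTE staff)"}
  DI2: {role: DI, unit: "1 bed"}
  UI1: {role: UI, unit: "% (in-patient discharge rate)"}
  DO1: {role: DO, unit: "1000 days (IP+DP length of stay)"}
  DO2: {role: DO, unit: "1000 persons (ED attendances)"}
  DO3: {role: DO, unit: "1000 persons (outpatient attendances)"}
  UO1: {role: UO, unit: "per mille (crude mortality rate)"}
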