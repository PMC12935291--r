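{
  "illiterate": {
    "time_orientation": 1,
    "space_orientation": 3,
    "immediate_memory": 2,
    "attention_calculation": 1,
    "delayed_memory": 2,
    "naming": 3,
    "repetition": 3,
    "execution_ability": 2,
    "reading": 3,
    "writing": 2,
    "spatial_structure": 3
  },
  "primary": {
    "time_orientation": 2,
    "space_orientation": 3,
    "immediate_memory": 2,
    "attention_calculation": 1,
    "delayed_memory": 2,
    "naming": 1,
    "repetition": 2,
    "execution_ability": 3,
    "reading": 2,
    "writing": 2,
    "spatial_structure": 1
  },
  "secondary": {
    "time_orientation": 2,
    "space_orientation": 3,
    "immediate_memory": 2,
    "attention_calculation": 2,
    "delayed_memory": 1,
    "naming": 2,
    "repetition": 2,
    "execution_ability": 2,
    "reading": 1,
    "writing": 1,
    "spatial_structure": 1
  },
  "university": {
    "time_orientation": 1,
    "space_orientation": 3,
    "immediate_memory": 2,
    "attention_calculation": 2,
    "delayed_memory": 2,
    "naming": 2,
    "repetition": 3,
    "execution_ability": 1,
    "reading": 1,
    "writing": 2,
    "spatial_structure": 2
  },
  "thresholds": {
    "illiterate": 30,
    "primary": 31,
    "secondary": 32,
    "university": 33
  }
}
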