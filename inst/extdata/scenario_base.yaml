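# Base deployment scenario: all selection inputs 0.5, starting resistance
# frequencies 0.01, no fitness costs, unlinked loci.
insecticide1:
  effectiveness: 0.5
  exposure: 0.5
  resistance_restoration: 0.5
  dominance_resistance: 0.5
  start_frequency: 0.01
  cost: 0
  dominance_cost: 0
insecticide2:
  effectiveness: 0.5
  exposure: 0.5
  resistance_restoration: 0.5
  dominance_resistance: 0.5
  start_frequency: 0.01
  cost: 0
  dominance_cost: 0
recombination_rate: 0.5
resistance_threshold: 0.5
max_generations: 500
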