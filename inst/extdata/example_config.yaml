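# example configuration for the command-line wrapper (inst/cli/mcepisodes.R)
states: [H, I, D]
absorbing: [D]
panel: toy_panel.csv          # long-format CSV: id, time, state
chain: illness_death_chain.csv
target: [I]
start: H
horizon: 60
step_length: 1
units: step
bootstrap:
  method: block
  replicates: 1000
  level: 0.95
  seed: 1
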