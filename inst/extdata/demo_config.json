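{
  "stage": "demo",
  "seed": 1234,
  "out_dir": "results/demo",
  "ga": {
    "population_size": 60,
    "crossover_fraction": 0.7,
    "mutation_rate": 0.8,
    "max_generations": 150
  }
}
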