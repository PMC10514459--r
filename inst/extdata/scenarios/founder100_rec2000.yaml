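label: founder100_rec2000
mainland_capacity: 50000.0
burnin_years: 500000.0
events:
- time: 7000
  kind: found_from_mainland
  population: island
  capacity: 100.0
- time: 6900
  kind: set_capacity
  population: island
  capacity: 2000.0
- time: 1200
  kind: set_capacity
  population: island
  capacity: 20000.0
- time: 200
  kind: set_capacity
  population: island
  capacity: 1800.0
- time: 100
  kind: set_capacity
  population: island
  capacity: 20000.0
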