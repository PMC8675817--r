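# Canonical tracking scenario: reference patient, GA-optimized MPC.
controller: ga_mpc
window: 200
sampling_time_s: 1
seed: 1
ref_amplitude: 1
dist_amplitude: 0
P: 20
M: 2
mu: 1
lambda: 0.1
u_min: 0
u_max: 2
horizon_shift: true
ga:
  population: 100
  generations: 10
  p_crossover: 0.7
  p_mutation: 0.005
  elite: 1
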