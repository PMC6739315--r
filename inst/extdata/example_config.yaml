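# Example run configuration. Every key is optional; omitted keys take the
# package defaults (see ?run_config and ?kinetics_params for units).
variant: HM1            # SM | USM | HM10 | HM1
duration: 21600         # stimulated steps (1 step = 1 s)
seed: 7
sampling_interval: 100  # record every 100th step
equilibration: 600      # unstimulated burn-in (s)
elastic:
  mu_cell: 1000         # Pa
  mu_ecm_base: 1000     # Pa
  sigma_far: 15.804852  # Pa; peak per-integrin force 10 pN at time zero
stiffening: power       # mu_ecm = mu_base * (1 + 0.001 n)^beta
beta: 1.56
ecmp_increment: 0.001
layout: fibonacci       # deterministic equal-area integrin placement
kinetics:
  prime_mean: 240       # mean stochastic integrin priming delay (s)
  basal_rate: 0.15      # spontaneous transient ERK activations per second
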