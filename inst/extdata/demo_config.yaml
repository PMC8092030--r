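# Demo configuration for run_pipeline(): a small synthetic four-phase
# corpus exercising every stage end to end.
seed: 42
simulate:
  n_posts_per_phase: 400
  n_users: 120
  bot_fraction: 0.03
  negation_prob: 0.1
preprocess:
  bot_percentile: 0.99
  dup_threshold: 1
  salt: demo
embedding:
  d: 50
  window: 5
  min_count: 3
  epochs: 5
lexicon:
  tau: 0.35
  k: 20
emotions:
  window: 3
topics:
  k: 4
  iters: 150
gsom:
  sf: 0.3
  alpha0: 0.3
  fd: 0.5
  growth_epochs: 15
  smooth_epochs: 15
compare:
  a: first_lockdown
  b: second_lockdown
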