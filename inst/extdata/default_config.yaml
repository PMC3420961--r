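# Full run configuration for addnet, with every tunable at its default.
# Any key may be omitted; omitted keys keep these values.

nmm:
  c1: 84.15            # excitatory -> inhibitory population coupling
  c2: 0.06             # inhibitory -> excitatory population coupling
  he_gain: 0.009333    # excitatory kernel amplitude (mV per pulse-density unit)
  he_decay: 55         # excitatory kernel slow rate (1/s)
  he_rise: 605         # excitatory kernel fast rate (1/s)
  hi_gain: 22          # inhibitory kernel amplitude (mV)
  hi_decay: 20         # inhibitory kernel slow rate (1/s)
  hi_rise: 45          # inhibitory kernel fast rate (1/s)
  sigmoid_e:           # excitatory potential -> rate sigmoid
    max_rate: 922      #   ceiling (spikes/s)
    threshold: 5.25    #   midpoint (mV)
    steepness: 0.93    #   slope (1/mV)
  sigmoid_i:           # inhibitory potential -> rate sigmoid
    max_rate: 450
    threshold: 6.90
    steepness: 1.4
  pt: 1                # thalamic input gain (degraded by the ADD rule)
  thalamic_mean: 64800 # thalamic pulse density mean (spikes/s)
  thalamic_sd: 9000    # thalamic pulse density sd (spikes/s)
  sample_rate: 500     # Hz; one sample is also the conduction delay

simulation:
  coupling_strength: 1.5  # global inter-mass coupling S
  epoch_samples: 4096     # samples per analysis epoch (8.2 s at 500 Hz)
  n_epochs: 1
  warmup_samples: 1000    # discarded start-up (2 s)
  seed: 42
  n_runs: 20              # ensemble size

degeneration:
  mode: add            # add (activity-dependent) or rd (uniform control)
  loss_rate: 1.5e-5    # rho: per-update, per-(spikes/s) damage rate
  loss_form: exponential  # exponential | linear
  n_updates: 100
  buffer_steps: 20     # activity-buffer length (samples)

sl:
  p_ref: 0.01          # reference recurrence probability
  ref_step: 4          # stride between reference time points
  max_embed_dim: 10    # cap on the auto-tuned embedding dimension
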