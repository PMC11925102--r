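# Synthetic-recording generator settings: 4-s epochs, 12h:12h light/dark,
# 1 Hz rocking encoded at twice the platform rate, habituating gain on the
# wake-to-NREM transition hazard. Omitted fields keep package defaults.
epoch_len: 4
lights_on: "20:00"
rocking_gain: 1.5
tau_within: 18      # hours of accumulated stimulation within a cycle
tau_across: 3       # cycles
rocking_freq: 1.0   # Hz
entrain_factor: 2
delta_peak_base: 3.0
sample_rate: 128
mean_dwell:         # mean bout durations, seconds
  light: {W: 96, NR: 160, R: 64}
  dark: {W: 400, NR: 128, R: 56}
motion_rate_wake: 6      # movement events/min awake
motion_gap_cap_wake: 20  # s, must stay < 40
twitch_rate_sleep: 0.2   # events/min asleep
seed: 1
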