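# riskplot pipeline configuration template.
# Any key may be omitted; omitted keys keep the package defaults shown here.
# Unknown keys are rejected.

preprocess:
  mains_freq: 50        # 50 or 60 Hz
  notch_q: 30           # notch quality factor (centre / -3 dB bandwidth)
  wavelet: db4          # db2 | db4 | db6 | db8
  level: 4              # decomposition depth
  detail_levels: [1, 2] # detail levels to soft-threshold (1 = finest)

detection:
  include_flagged: false # project quality-flagged intervals too
  refractory: 0.2        # minimum R-R separation (s)

rp:
  stair_min: 0.3        # first stair edge (s)
  stair_max: 1.5        # last stair edge (s)
  stair_width: 0.01     # stair width (s)
  drain_rate: 1         # tokens drained per stair per beat
  capacity: 8           # occupancy at which a spring fails
  window_beats: 300     # beats per analysis window
  oor_policy: clamp     # clamp | drop

index:
  weights:
    concentration: 0.4
    stuck: 0.4
    throughput: 0.2
  thresholds:
    amber: 0.20
    red: 0.25

output:
  plots: true

log_level: info         # info | quiet
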