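# example run configuration (detect mode)
mode: detect
recordings: recordings.csv
segments: segments_example.csv
subjects: subjects.csv
upper: Fp1
lower: Ve1
fs: 500
threshold_uv: 100
min_interval_ms: 250
filter.low_cut_hz: 0.5
filter.high_cut_hz: 20
filter.order: 4
filter.zero_phase: true
seed: 1
out_dir: out
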