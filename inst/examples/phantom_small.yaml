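# Miniature end-to-end phantom study: two-round weak training plus the
# fully supervised baseline, compared on held-out test patients.
seed: 1
phantom:
  n_patients: 30
  image_size: 64
  n_modalities: 2
  n_slices: 3
split:
  fractions: [0.8, 0.0, 0.2]
n_annotated: 4
weak_labels:
  p1: 0.9
  p2: 1.2
  dilation: 1.05
net:
  channels: [8, 16, 32, 64, 128]
train:
  learning_rate: 0.02
  batch_size: 8
  epochs_round1: 8
  epochs_round2: 12
baseline: true
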