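# Example training configuration for `sonocaliper train-detector` /
# `train-heatmap` (values shown are the package defaults used by the
# desk-scale study; --seed on the command line overrides the seed).
epochs: 30
batch_size: 8
learning_rate: 0.003
lambda_nobj: 0.5
anchor: 32
# heatmap-only settings
crop_size: 48
jitter: 0.06
n_aug: 2
hm_widths: [8, 16, 32, 64]
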