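# demo configuration: a small simulated study
n_subjects=2
epochs_per_subject=30
n_channels=8
p_error=0.3
snr=3
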