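# Study configuration for the demonstration workflow.
# The trial protocol follows the kinesthetic motor-imagery design:
# 6 s rest / 2 s warning / 4 s imagery, 40 trials, 256 Hz, 32 EEG channels.
n_subjects: 12
n_trials: 40
fs: 256
seed: 20260101
# latent correlation between manual-activity frequency and ERD depth;
# 0 reproduces a null scenario, 0.6 a positive-association scenario
manual_corr: 0.6
# classifier evaluation
methods: [csp_lda, mdrm, gfmdrm, tslr]
k_folds: 4
# ERSP group comparison
n_perm: 1000
alpha: 0.05
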