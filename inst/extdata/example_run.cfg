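# Example swayval simulation configuration (key = value).
# Study design
n_subjects = 20
n_trials = 3
conditions = EO,EC
directions = ML,AP
seed = 1

# Latent sway process
theta = 8            # mean-reversion rate, 1/s
sigma_base = 0.3     # baseline sway SD, cm
ec_multiplier = 1.4  # eyes-closed amplitude factor
tau2 = 0.06          # between-subject log-amplitude variance
omega2 = 0.04        # within-subject (trial) log-amplitude variance
duration = 20        # s
fp_rate = 200        # Hz
vr_rate = 10         # Hz
ap_anisotropy = 1.2

# Headset observation model
gain = 1.5
smooth_cutoff = 1    # Hz
jitter_sd = 0.25     # cm
drift_sd = 0.1       # cm
jitter_subj_sd = 0.25
jitter_trial_sd = 0.34
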