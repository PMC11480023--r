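#!/usr/bin/env Rscript
# Step 1 — simulate the study dataset.
#
# A patient-structured, imbalanced EEG corpus in the shape of a clinical
# seizure archive: 19-channel 10/20-style montage at 250 Hz, 4-s epochs,
# ~6% of epochs carrying a 3 Hz spike-wave-like burst on a third of the
# channels. 20 patients x 30 epochs keeps the desk-scale run tractable.
# Writes per-patient EDF files + label sidecar + manifest under
# results/data/.

library(eegaug)

cfg <- sim_config(n_patients = 20, epochs_per_patient = 30, n_channels = 19,
                  fs = 250, epoch_seconds = 4, seizure_fraction = 0.06,
                  seed = 20260922L)
man <- run_simulate(cfg, "results/data", format = "edf")
cat(sprintf("simulated %d epochs (%d seizure, %.1f%%) for %d patients -> results/data\n",
            man$n_epochs, man$n_seizure, 100 * man$n_seizure / man$n_epochs,
            man$n_patients))
cat("manifest hash:", man$config_hash, "\n")
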