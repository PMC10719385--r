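# Preprocess both modalities to 200 Hz band-power envelopes (demean ->
# 25-100 Hz band-pass -> 49-51 Hz band-stop -> Hilbert envelope ->
# resample) and export movement-locked average envelopes per class and
# channel -- the sanity view that radial channels respond to DII and ulnar
# channels to DV, with a transient confined to the 1 s movement.

source("analysis/00_config.R")

experiment <- default_experiment()
env_emg <- preprocess_modality(experiment, "EMG")
env_mmg <- preprocess_modality(experiment, "MMG")

for (mod in list(list(name = "EMG", env = env_emg),
                 list(name = "MMG", env = env_mmg))) {
  for (lab in c("DII", "DV")) {
    avg <- movement_locked_average(mod$env, lab, window = c(-0.25, 2))
    write_tsv(avg, sprintf("movement_locked_%s_%s.tsv", mod$name, lab))
  }
  for (s in seq_along(mod$env$sessions))
    write_recording(mod$env$sessions[[s]],
                    file.path(SCRATCH_DIR,
                              sprintf("env_%s_s%d", tolower(mod$name), s)))
}

# quick numeric summary: movement-window vs rest-window envelope RMS
contrast <- do.call(rbind, lapply(
  list(EMG = env_emg, MMG = env_mmg), function(env) {
    ratios <- sapply(seq_along(env$sessions), function(s) {
      on <- round(env$events[[s]]$onset * env$fs)
      dat <- env$sessions[[s]]$data
      move <- unlist(lapply(on, function(i) dat[, (i + 1):(i + 200)]))
      rest <- unlist(lapply(on, function(i) dat[, (i + 501):(i + 800)]))
      sqrt(mean(move^2)) / sqrt(mean(rest^2))
    })
    data.frame(modality = env$channels$modality[1],
               move_rest_rms_ratio = mean(ratios))
  }))
write_tsv(contrast, "envelope_contrast.tsv")
print(contrast)
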