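# Train and evaluate the residual 1-D convolutional classifier on both
# modalities under stratified 5-fold cross-validation (500/100 windows per
# class and split, 100 epochs), with identical window positions for EMG
# and MMG so their predictions are aligned. Exports per-fold accuracies,
# pooled confusion matrices, loss curves, per-window predictions and
# integrated-gradients channel importances.

source("analysis/00_config.R")

experiment <- default_experiment()
envs <- list(EMG = preprocess_modality(experiment, "EMG"),
             MMG = preprocess_modality(experiment, "MMG"))

cv <- cross_validate(envs, model_config(), k = 5, n_train = 500,
                     n_test = 100, epochs = 100, seed = MASTER_SEED)

acc <- do.call(rbind, lapply(names(cv$modalities), function(mod) {
  folds <- cv$modalities[[mod]]$folds
  data.frame(modality = mod, fold = seq_along(folds),
             accuracy = vapply(folds, function(f) f$accuracy, numeric(1)))
}))
write_tsv(acc, "fold_accuracy.tsv")
message(sprintf("mean accuracy: EMG %.4f, MMG %.4f",
                cv$modalities$EMG$accuracy, cv$modalities$MMG$accuracy))

for (mod in names(cv$modalities)) {
  cm <- as.data.frame.matrix(cv_confusion(cv, mod))
  write_tsv(cbind(true = rownames(cm), cm),
            sprintf("confusion_%s.tsv", mod))
  lc <- do.call(cbind, lapply(cv$modalities[[mod]]$folds,
                              function(f) f$loss_curve))
  colnames(lc) <- paste0("fold", seq_len(ncol(lc)))
  write_tsv(cbind(epoch = seq_len(nrow(lc)), as.data.frame(lc)),
            sprintf("loss_curves_%s.tsv", mod))
  preds <- do.call(rbind, lapply(cv$modalities[[mod]]$folds, function(f)
    cbind(fold = f$fold, f$predictions)))
  write_tsv(preds, sprintf("predictions_%s.tsv", mod))
  imp <- cv_channel_importance(cv, mod, envs[[mod]]$channels, m = 6)
  write_tsv(imp, sprintf("importance_%s.tsv", mod))
}
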