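# Statistics over the decoding results: between-modality agreement
# (consensus matrix, percentage agreement, Cohen's kappa), the McNemar
# comparison on aligned predictions, the 5x2-CV F-test, and the
# permutation-based empirical chance level with p-values and Cohen's d.
#
# Reads the aligned per-window predictions written by 03_decode.R; the
# 5x2 test and the permutation null retrain models at reduced scale.

source("analysis/00_config.R")

preds_emg <- utils::read.delim(file.path(RESULTS_DIR, "predictions_EMG.tsv"))
preds_mmg <- utils::read.delim(file.path(RESULTS_DIR, "predictions_MMG.tsv"))
stopifnot(identical(preds_emg$true, preds_mmg$true))
classes <- c("DII", "DV", "NoMove")

acc <- utils::read.delim(file.path(RESULTS_DIR, "fold_accuracy.tsv"))
acc_obs <- tapply(acc$accuracy, acc$modality, mean)

cons <- consensus_matrix(preds_emg$pred, preds_mmg$pred, classes)
agree <- percentage_agreement(preds_emg$pred, preds_mmg$pred)
kap <- cohens_kappa(preds_emg$pred, preds_mmg$pred, classes)
mcn <- mcnemar_test(preds_emg$pred, preds_mmg$pred, preds_emg$true)
message(sprintf("agreement %.2f%%, kappa %.3f, McNemar chi2(1) = %.2f (p = %.3g, g = %.2f)",
                agree, kap, mcn$chi2, mcn$p, mcn$g))
write_tsv(cbind(EMG = rownames(cons), as.data.frame.matrix(cons)),
          "consensus_matrix.tsv")

# 5x2-CV F-test comparing the modalities on identical trial splits
experiment <- default_experiment()
envs <- list(EMG = preprocess_modality(experiment, "EMG"),
             MMG = preprocess_modality(experiment, "MMG"))
builder <- function(env) mmgdecode:::modality_builder(
  env, model_config(), n_train = 250, n_test = 100, epochs = 40)
fxt <- five_by_two_cv_ftest(builder(envs$EMG), builder(envs$MMG),
                            envs$EMG$trials,
                            seed = derive_seed(MASTER_SEED, 42L))
message(sprintf("5x2-CV: F(10,5) = %.2f, p = %.3g", fxt$f, fxt$p))

# permutation null (reduced scale) and effect sizes
nulls <- lapply(names(envs), function(mod) permutation_null(
  function(perm_seed) cross_validate(
    envs[[mod]], model_config(), k = 2, n_train = 100, n_test = 50,
    epochs = 10, seed = perm_seed,
    permute_train = TRUE)$modalities[[1]]$accuracy,
  n_perm = 30, seed = derive_seed(MASTER_SEED, 77L, match(mod, names(envs))),
  statistic = paste0("accuracy_", mod)))
names(nulls) <- names(envs)

stats_out <- do.call(rbind, lapply(names(envs), function(mod) {
  pv <- perm_pvalue(acc_obs[[mod]], nulls[[mod]])
  data.frame(modality = mod,
             accuracy = acc_obs[[mod]],
             null_mean = mean(nulls[[mod]]$values),
             p_display = pv$display,
             cohens_d = cohens_d_vs_null(acc_obs[[mod]], nulls[[mod]]))
}))
print(stats_out)
write_tsv(stats_out, "chance_level.tsv")
write_tsv(data.frame(statistic = c("percent_agreement", "kappa",
                                   "mcnemar_chi2", "mcnemar_g",
                                   "f_5x2"),
                     value = c(agree, kap, mcn$chi2, mcn$g, fxt$f),
                     p = c(NA, NA, mcn$p, NA, fxt$p)),
          "comparison_statistics.tsv")
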