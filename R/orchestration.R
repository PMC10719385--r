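# End-to-end driver: simulate -> preprocess -> cross-validate both
# modalities -> attribution -> agreement -> classifier comparison ->
# optional permutation null, with provenance and optional on-disk report.

#' Configuration of a full analysis run
#'
#' @param generator a [generator_config()].
#' @param model a [model_config()] (channel count is adapted per modality).
#' @param k cross-validation folds.
#' @param n_train,n_test windows per class per split.
#' @param epochs training epochs for the main cross-validation.
#' @param m_ig integrated-gradients interpolation levels.
#' @param n_perm permutations for the empirical chance level (0 skips the
#'   permutation stage).
#' @param perm_scale list of reduced settings used inside the permutation
#'   loop (`k`, `n_train`, `n_test`, `epochs`); the full protocol at 1000
#'   permutations is available but far beyond a desk-scale run.
#' @param run_five_by_two run the 5x2-CV F-test comparing the modalities.
#' @param five_by_two_scale list of reduced settings (`n_train`, `n_test`,
#'   `epochs`) for the ten trainings per modality of the 5x2 test.
#' @param seed master seed for every stochastic stage.
#' @return object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       model = model_config(),
                       k = 5L, n_train = 500L, n_test = 100L,
                       epochs = 100L, m_ig = 6L, n_perm = 0L,
                       perm_scale = list(k = 2L, n_train = 100L,
                                         n_test = 50L, epochs = 15L),
                       run_five_by_two = TRUE,
                       five_by_two_scale = list(n_train = 250L,
                                                n_test = 100L,
                                                epochs = 40L),
                       seed = 1L) {
  structure(list(generator = generator, model = model, k = as.integer(k),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 epochs = as.integer(epochs), m_ig = as.integer(m_ig),
                 n_perm = as.integer(n_perm), perm_scale = perm_scale,
                 run_five_by_two = isTRUE(run_five_by_two),
                 five_by_two_scale = five_by_two_scale,
                 seed = as.integer(seed)),
            class = "run_config")
}

# builder closure for the 5x2 comparison: trains one model of the given
# modality on the supplied trials and returns its test accuracy.
modality_builder <- function(envexp, cfg, n_train, n_test, epochs) {
  force(envexp); force(cfg)
  function(train_trials, test_trials, seed) {
    ds <- build_fold_dataset(envexp,
                             list(train = train_trials, test = test_trials),
                             n_train, n_test, seed = seed)
    mcfg <- cfg
    mcfg$C <- dim(ds$train$X)[3]
    mcfg$seed <- derive_seed(seed, 33L)
    model <- train_model(build_model(mcfg), ds$train$X, ds$train$y,
                         epochs = epochs)
    mean(predict(model, ds$test$X, type = "class") ==
           as.character(ds$test$y))
  }
}

#' Run the complete decoding analysis
#'
#' Generates (or accepts) a synthetic experiment, preprocesses both
#' modalities, trains and evaluates the classifier under stratified k-fold
#' cross-validation with shared window positions across modalities,
#' computes integrated-gradients channel importances, between-modality
#' agreement (consensus matrix, percentage agreement, Cohen's kappa), the
#' McNemar comparison, optionally the 5x2-CV F-test and the permutation
#' chance level. Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [run_config()].
#' @param experiment optional pre-generated `mmg_experiment` (otherwise
#'   generated from `cfg$generator` and `cfg$seed`).
#' @param out_dir optional directory; when given, report tables are written
#'   as TSV/JSON with checksums recorded in the provenance block.
#' @param verbose print stage progress.
#' @return object of class `run_report`.
#' @export
run_full_analysis <- function(cfg, experiment = NULL, out_dir = NULL,
                              verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  say("simulate")
  experiment <- experiment %||%
    stage("simulate", generate_experiment(cfg$generator, cfg$seed))
  say("preprocess")
  env_emg <- stage("preprocess", preprocess_modality(experiment, "EMG"))
  env_mmg <- stage("preprocess", preprocess_modality(experiment, "MMG"))
  envs <- list(EMG = env_emg, MMG = env_mmg)

  say("cross-validate")
  cv <- stage("cross_validate",
              cross_validate(envs, cfg$model, k = cfg$k,
                             n_train = cfg$n_train, n_test = cfg$n_test,
                             epochs = cfg$epochs, seed = cfg$seed))
  accuracy <- lapply(cv$modalities, function(m) m$accuracy)
  fold_acc <- lapply(cv$modalities, function(m)
    vapply(m$folds, function(f) f$accuracy, numeric(1)))
  confusion <- list(EMG = cv_confusion(cv, "EMG"),
                    MMG = cv_confusion(cv, "MMG"))
  loss_curves <- lapply(cv$modalities, function(m)
    do.call(cbind, lapply(m$folds, function(f) f$loss_curve)))

  say("attribution")
  importance <- stage("attribution", list(
    EMG = cv_channel_importance(cv, "EMG", env_emg$channels, m = cfg$m_ig),
    MMG = cv_channel_importance(cv, "MMG", env_mmg$channels, m = cfg$m_ig)
  ))

  say("agreement")
  preds <- lapply(cv$modalities, function(m)
    do.call(rbind, lapply(m$folds, function(f) f$predictions)))
  agreement <- stage("agreement", list(
    consensus = consensus_matrix(preds$EMG$pred, preds$MMG$pred,
                                 cv$classes),
    percent = percentage_agreement(preds$EMG$pred, preds$MMG$pred),
    kappa = cohens_kappa(preds$EMG$pred, preds$MMG$pred, cv$classes)
  ))
  mcnemar <- stage("mcnemar",
                   mcnemar_test(preds$EMG$pred, preds$MMG$pred,
                                preds$EMG$true))

  five_by_two <- NULL
  if (cfg$run_five_by_two) {
    say("5x2 CV F-test")
    s <- cfg$five_by_two_scale
    five_by_two <- stage("five_by_two", five_by_two_cv_ftest(
      modality_builder(env_emg, cfg$model, s$n_train, s$n_test, s$epochs),
      modality_builder(env_mmg, cfg$model, s$n_train, s$n_test, s$epochs),
      env_emg$trials, seed = derive_seed(cfg$seed, 444L)))
  }

  permutation <- list(skipped = TRUE)
  if (cfg$n_perm > 0L) {
    say("permutation null (%d permutations)", cfg$n_perm)
    s <- cfg$perm_scale
    permutation <- stage("permutation", {
      nulls <- lapply(names(envs), function(mod) {
        permutation_null(function(perm_seed) {
          cross_validate(envs[[mod]], cfg$model, k = s$k,
                         n_train = s$n_train, n_test = s$n_test,
                         epochs = s$epochs, seed = perm_seed,
                         permute_train = TRUE)$modalities[[1]]$accuracy
        }, n_perm = cfg$n_perm,
        seed = derive_seed(cfg$seed, 555L, match(mod, names(envs))),
        statistic = paste0("accuracy_", mod))
      })
      names(nulls) <- names(envs)
      list(
        skipped = FALSE,
        null = nulls,
        p = lapply(names(envs), function(mod)
          perm_pvalue(accuracy[[mod]], nulls[[mod]])),
        d = lapply(names(envs), function(mod)
          cohens_d_vs_null(accuracy[[mod]], nulls[[mod]]))
      )
    })
    names(permutation$p) <- names(envs)
    names(permutation$d) <- names(envs)
  }

  report <- structure(list(
    accuracy = accuracy, fold_accuracy = fold_acc, confusion = confusion,
    loss_curves = loss_curves, importance = importance,
    agreement = agreement, mcnemar = mcnemar, five_by_two = five_by_two,
    permutation = permutation,
    provenance = list(
      seed = cfg$seed,
      config_hash = config_hash(cfg),
      package_version = as.character(utils::packageVersion("mmgdecode")),
      timestamp = format(Sys.time(), tz = "UTC"),
      files = NULL
    )
  ), class = "run_report")
  if (!is.null(out_dir)) report <- write_report(report, out_dir)
  report
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(cfg[setdiff(names(cfg), "seed")]), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  accuracy: EMG %.4f, MMG %.4f\n",
              x$accuracy$EMG, x$accuracy$MMG))
  cat(sprintf("  agreement: %.2f%%, kappa %.3f\n",
              x$agreement$percent, x$agreement$kappa))
  cat(sprintf("  McNemar: chi2(1) = %.3f, p = %.3g, g = %.3f\n",
              x$mcnemar$chi2, x$mcnemar$p, x$mcnemar$g))
  if (!is.null(x$five_by_two))
    cat(sprintf("  5x2-CV: F(10,5) = %.3f, p = %.3g\n",
                x$five_by_two$f, x$five_by_two$p))
  if (!isTRUE(x$permutation$skipped))
    cat(sprintf("  permutation null: EMG p %s, MMG p %s\n",
                x$permutation$p$EMG$display, x$permutation$p$MMG$display))
  else cat("  permutation stage skipped (n_perm = 0)\n")
  invisible(x)
}

#' Movement-locked average envelope
#'
#' Per-channel mean envelope time course, time-locked to the movement
#' onsets of one class across all sessions.
#'
#' @param envexp an `envelope_experiment`.
#' @param label movement class (`"DII"` or `"DV"`).
#' @param window `(pre_s, post_s)` in seconds around onset (pre negative).
#' @return data.frame `time` (s relative to onset), one column per channel.
#' @export
movement_locked_average <- function(envexp, label, window = c(-1, 2)) {
  fs <- envexp$fs
  i_pre <- round(window[1] * fs)
  i_post <- round(window[2] * fs)
  segs <- list()
  for (s in seq_along(envexp$events)) {
    ev <- envexp$events[[s]]
    rows <- which(ev$label == label)
    env <- envexp$sessions[[s]]$data
    for (r in rows) {
      i0 <- round(ev$onset[r] * fs)
      idx <- (i0 + i_pre):(i0 + i_post)
      if (idx[1] < 0 || idx[length(idx)] >= ncol(env))
        stopf("averaging window outside the recording for an event at %.2f s", ev$onset[r])
      segs[[length(segs) + 1L]] <- env[, idx + 1L, drop = FALSE]
    }
  }
  if (!length(segs)) stopf("no events of class %s", label)
  avg <- Reduce(`+`, segs) / length(segs)
  out <- data.frame(time = (i_pre:i_post) / fs)
  mat <- t(avg)
  colnames(mat) <- envexp$channels$name
  cbind(out, as.data.frame(mat, optional = TRUE))
}
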