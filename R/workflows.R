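#' Experiment specification
#'
#' Bundles the classifier configuration and the repetition protocol of one
#' experiment.  Repetition `r` trains with seed `base_seed + r - 1`; run
#' variance thus comes from network initialization, batching and
#' augmentation, as in repeated-training protocols.
#'
#' @param method One of `"train_time_calib"`, `"test_time_calib"`,
#'   `"no_calib_train_stats"`, `"no_calib_calibrated_stats"`,
#'   `"no_calib_test_stats"`, `"fine_tune"`, `"auc_analysis"`, `"bn_freeze"`.
#' @param config A [classifier_config()].
#' @param n_repetitions Number of repeated trainings (default 10).
#' @param base_seed First repetition seed.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(method = c("train_time_calib", "test_time_calib",
                                       "no_calib_train_stats",
                                       "no_calib_calibrated_stats",
                                       "no_calib_test_stats", "fine_tune",
                                       "auc_analysis", "bn_freeze"),
                            config = classifier_config(),
                            n_repetitions = 10L, base_seed = 100L) {
  structure(list(method = match.arg(method), config = config,
                 n_repetitions = as.integer(n_repetitions),
                 base_seed = as.integer(base_seed)),
            class = "experiment_spec")
}

rep_config <- function(spec, r) {
  cfg <- spec$config
  cfg$seed <- derive_seed(spec$base_seed, r)
  cfg
}

#' Aggregate repeated evaluation results into an experiment report
#'
#' @param results List of `eval_result`s (one per repetition), or a data
#'   frame with columns `accuracy` and `auc`.
#' @param method Label for the report.
#' @return An `experiment_report`: per-run table plus mean and population
#'   standard deviation of accuracy and AUC.
#' @export
repeat_and_aggregate <- function(results, method = "experiment") {
  runs <- if (is.data.frame(results)) results
          else data.frame(rep = seq_along(results),
                          accuracy = vapply(results, `[[`, numeric(1), "accuracy"),
                          auc = vapply(results, `[[`, numeric(1), "auc"),
                          threshold = vapply(results, `[[`, numeric(1), "threshold"))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(list(method = method, runs = runs,
                 mean_accuracy = mean(runs$accuracy),
                 sd_accuracy = pop_sd(runs$accuracy),
                 mean_auc = mean(runs$auc), sd_auc = pop_sd(runs$auc)),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s: accuracy %.2f +/- %.2f %%, AUC %.4f +/- %.4f (%d runs)\n",
              x$method, x$mean_accuracy, x$sd_accuracy, x$mean_auc, x$sd_auc,
              nrow(x$runs)))
  invisible(x)
}

#' Train-time calibration (calibrate the training data)
#'
#' The training patches are moved into the testing domain with the forward
#' transfer function; z-score statistics are computed from the transformed
#' set and used both to normalize the training input and, at evaluation, the
#' incoming test patches -- so no statistic is taken from the raw test data.
#' A fresh model is trained per repetition.
#'
#' @param train_patches,test_patches Labeled `patch_set`s from the training
#'   and testing machines (test patches already on the shared grid).
#' @param tf_fwd Train-to-test `m2m_tf` (Wiener-regularized).
#' @param spec An [experiment_spec()].
#' @return An `experiment_report`.
#' @export
run_train_time_calibration <- function(train_patches, test_patches, tf_fwd, spec) {
  if (inherits(tf_fwd, "m2m_calibration")) tf_fwd <- tf_fwd$forward
  if (tf_fwd$direction != "train_to_test")
    stop("train-time calibration needs a train_to_test transfer function")
  x_tt <- apply_transfer(train_patches, tf_fwd)
  stats_cal <- compute_zscore_stats(x_tt, "calibrated")
  x_tt <- apply_zscore(x_tt, stats_cal)
  test_n <- apply_zscore(test_patches, stats_cal)
  results <- lapply(seq_len(spec$n_repetitions), function(r) {
    cfg <- rep_config(spec, r)
    model <- train_model(build_model(cfg), x_tt, cfg)
    evaluate_model(model, test_n)
  })
  repeat_and_aggregate(results, "train_time_calib")
}

#' Test-time calibration (calibrate the incoming test data)
#'
#' The model is trained on the raw training domain with training statistics;
#' at evaluation the test patches are moved into the training domain with
#' the backward transfer function and normalized with the training
#' statistics.  An already-trained model can be reused: no retraining is
#' needed per calibration.
#'
#' @inheritParams run_train_time_calibration
#' @param tf_bwd Test-to-train `m2m_tf`.
#' @param models Optional list of pretrained `rf_classifier`s (one per
#'   repetition), e.g. the no-calibration models; when supplied no training
#'   happens here.
#' @return An `experiment_report`.
#' @export
run_test_time_calibration <- function(train_patches, test_patches, tf_bwd, spec,
                                      models = NULL) {
  if (inherits(tf_bwd, "m2m_calibration")) tf_bwd <- tf_bwd$backward
  if (tf_bwd$direction != "test_to_train")
    stop("test-time calibration needs a test_to_train transfer function")
  stats_train <- compute_zscore_stats(train_patches, "train")
  x_ttr <- apply_zscore(apply_transfer(test_patches, tf_bwd), stats_train)
  train_n <- if (is.null(models)) apply_zscore(train_patches, stats_train)
  results <- lapply(seq_len(spec$n_repetitions), function(r) {
    cfg <- rep_config(spec, r)
    model <- if (!is.null(models)) models[[r]]
             else train_model(build_model(cfg), train_n, cfg)
    evaluate_model(model, x_ttr)
  })
  repeat_and_aggregate(results, "test_time_calib")
}

#' No-calibration experiments with selectable normalization statistics
#'
#' Trains on the raw training domain (training statistics) and evaluates on
#' the raw test domain normalized with the selected statistics: `"train"`
#' (the worst case: nothing is adapted), `"calibrated"` (statistics of the
#' train-to-test transformed training set -- calibration applied to the
#' normalization only), or `"test"` (true test statistics: idealized
#' adaptation of the input normalization).
#'
#' @inheritParams run_train_time_calibration
#' @param stats_source `"train"`, `"calibrated"` or `"test"`.
#' @param tf_fwd Required for `stats_source = "calibrated"`.
#' @return An `experiment_report`.
#' @export
run_no_calibration <- function(train_patches, test_patches,
                               stats_source = c("train", "calibrated", "test"),
                               spec, tf_fwd = NULL) {
  stats_source <- match.arg(stats_source)
  stats_train <- compute_zscore_stats(train_patches, "train")
  eval_stats <- switch(stats_source,
    train = stats_train,
    calibrated = {
      if (is.null(tf_fwd)) stop("calibrated statistics need a train_to_test transfer function")
      if (inherits(tf_fwd, "m2m_calibration")) tf_fwd <- tf_fwd$forward
      compute_zscore_stats(apply_transfer(train_patches, tf_fwd), "calibrated")
    },
    test = compute_zscore_stats(test_patches, "test"))
  train_n <- apply_zscore(train_patches, stats_train)
  test_n <- apply_zscore(test_patches, eval_stats)
  results <- lapply(seq_len(spec$n_repetitions), function(r) {
    cfg <- rep_config(spec, r)
    model <- train_model(build_model(cfg), train_n, cfg)
    evaluate_model(model, test_n)
  })
  repeat_and_aggregate(results, paste0("no_calib_", stats_source, "_stats"))
}

#' Exact two-sided Wilcoxon signed-rank comparison of paired runs
#'
#' Paired by repetition index; zero differences are dropped (classic
#' convention).  For up to 25 nonzero differences the exact null
#' distribution of the signed midrank sum is computed by dynamic programming
#' (valid under ties); beyond that a normal approximation with tie-corrected
#' variance is used.
#'
#' @param runs_a,runs_b Equal-length (>= 5) numeric vectors of a per-run
#'   metric.
#' @return Two-sided p-value.
#' @export
wilcoxon_compare <- function(runs_a, runs_b) {
  if (length(runs_a) != length(runs_b)) stop("runs must be paired (equal length)")
  if (length(runs_a) < 5L) stop("need at least 5 paired runs")
  d <- runs_a - runs_b
  d <- d[d != 0]
  if (!length(d)) stop("degenerate comparison: all paired differences are zero")
  n <- length(d)
  r2 <- 2 * rank(abs(d))                 # doubled midranks are integers
  w <- sum(r2[d > 0])
  s <- sum(r2)
  if (n <= 25L) {
    counts <- numeric(s + 1L)            # counts[k+1] = #sign vectors with sum k
    counts[1L] <- 1
    for (wi in r2) {
      shifted <- c(numeric(wi), counts[seq_len(s + 1L - wi)])
      counts <- counts + shifted
    }
    total <- 2^n
    p_ge <- sum(counts[seq(w + 1L, s + 1L)]) / total
    p_le <- sum(counts[seq_len(w + 1L)]) / total
    min(1, 2 * min(p_ge, p_le))
  } else {
    mu <- s / 2
    sig <- sqrt(sum(r2^2) / 4)
    min(1, 2 * stats::pnorm(-abs(w - mu) / sig))
  }
}

#' Run the full method comparison on a simulated study
#'
#' Executes the calibration experiments and baselines on one
#' [simulate_study()] bundle, reusing work the way the underlying protocols
#' allow: per repetition, the no-calibration model (trained on the raw
#' training domain with training statistics) is shared by the three
#' no-calibration variants, test-time calibration, the AUC-threshold
#' baseline and fine-tuning initialization, while train-time calibration and
#' BN freezing train their own models.  Fine-tuning unfreezes the trailing
#' layers on the adaptation patches (normalized, like its evaluation, with
#' adaptation statistics); the AUC-threshold baseline rethresholds the
#' pretrained model using the adaptation set under training statistics; BN
#' freezing is evaluated with test statistics (the one baseline that assumes
#' them known).
#'
#' @param study An `m2m_study` from [simulate_study()].
#' @param config A [classifier_config()] shared by all arms.
#' @param n_repetitions Repeated trainings per method.
#' @param base_seed Seed of the first repetition.
#' @param methods Subset of methods to run (default all eight).
#' @param calibration `"stable"` or `"freehand"`: which calibration
#'   acquisition provides the transfer function.
#' @param tfs Optionally a precomputed [build_bidirectional()] result,
#'   overriding `calibration`.
#' @return Named list of `experiment_report`s.
#' @export
run_method_comparison <- function(study, config = classifier_config(),
                                  n_repetitions = 3L, base_seed = 100L,
                                  methods = c("no_calib_train_stats",
                                              "no_calib_calibrated_stats",
                                              "no_calib_test_stats",
                                              "auc_analysis", "fine_tune",
                                              "bn_freeze", "train_time_calib",
                                              "test_time_calib"),
                                  calibration = c("stable", "freehand"),
                                  tfs = NULL, config_ft = config) {
  stopifnot(inherits(study, "m2m_study"))
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(tfs)) {
    calibration <- match.arg(calibration)
    cs <- study$calib[[calibration]]
    tfs <- build_bidirectional(cs$train, cs$test)
  }
  needs_base <- any(methods %in% c("no_calib_train_stats", "no_calib_calibrated_stats",
                                   "no_calib_test_stats", "auc_analysis",
                                   "fine_tune", "test_time_calib"))

  # Statistics are computed once; large normalized/transformed patch sets are
  # rebuilt transiently per use so that peak memory stays near the size of
  # the study itself.
  stats_train <- compute_zscore_stats(study$train, "train")
  stats_test <- compute_zscore_stats(study$test, "test")
  stats_adapt <- compute_zscore_stats(study$adapt, "test")
  stats_cal <- local({
    x_tt <- apply_transfer(study$train, tfs$forward)
    compute_zscore_stats(x_tt, "calibrated")
  })
  gc(FALSE)

  res <- lapply(methods, function(m) vector("list", n_repetitions))
  names(res) <- methods
  for (r in seq_len(n_repetitions)) {
    cfg <- classifier_config(architecture = config$architecture,
                             bn_mode = config$bn_mode,
                             learning_rate = config$learning_rate,
                             epochs = config$epochs,
                             batch_size = config$batch_size,
                             hflip_prob = config$hflip_prob,
                             eval_batch_size = config$eval_batch_size,
                             seed = derive_seed(base_seed, r))
    m0 <- NULL
    if (needs_base) {
      train_n <- apply_zscore(study$train, stats_train)
      m0 <- train_model(build_model(cfg), train_n, cfg)
      rm(train_n); gc(FALSE)
    }
    if (any(methods %in% c("no_calib_train_stats", "auc_analysis"))) {
      test_n_train <- apply_zscore(study$test, stats_train)
      scores <- predict_scores(m0, test_n_train)
      labels <- test_n_train$info$class_label
      if ("no_calib_train_stats" %in% methods)
        res$no_calib_train_stats[[r]] <- eval_from_scores(scores, labels, 0.5)
      if ("auc_analysis" %in% methods) {
        th <- auc_threshold(m0, apply_zscore(study$adapt, stats_train))
        res$auc_analysis[[r]] <- eval_from_scores(scores, labels, th)
      }
      rm(test_n_train); gc(FALSE)
    }
    if ("no_calib_calibrated_stats" %in% methods) {
      res$no_calib_calibrated_stats[[r]] <-
        evaluate_model(m0, apply_zscore(study$test, stats_cal))
      gc(FALSE)
    }
    if ("no_calib_test_stats" %in% methods) {
      res$no_calib_test_stats[[r]] <-
        evaluate_model(m0, apply_zscore(study$test, stats_test))
      gc(FALSE)
    }
    if ("test_time_calib" %in% methods) {
      x_ttr_n <- apply_zscore(apply_transfer(study$test, tfs$backward), stats_train)
      res$test_time_calib[[r]] <- evaluate_model(m0, x_ttr_n)
      rm(x_ttr_n); gc(FALSE)
    }
    if ("fine_tune" %in% methods) {
      cfg_ft <- config_ft
      cfg_ft$seed <- cfg$seed
      mft <- fine_tune(m0, apply_zscore(study$adapt, stats_adapt), cfg_ft)
      res$fine_tune[[r]] <- evaluate_model(mft, apply_zscore(study$test, stats_adapt))
      rm(mft); gc(FALSE)
    }
    rm(m0); gc(FALSE)
    if ("bn_freeze" %in% methods) {
      cfg_bn <- cfg; cfg_bn$bn_mode <- "frozen"
      train_n <- apply_zscore(study$train, stats_train)
      mbn <- train_model(build_model(cfg_bn), train_n, cfg_bn)
      rm(train_n)
      res$bn_freeze[[r]] <- evaluate_model(mbn, apply_zscore(study$test, stats_test))
      rm(mbn); gc(FALSE)
    }
    if ("train_time_calib" %in% methods) {
      x_tt_n <- apply_zscore(apply_transfer(study$train, tfs$forward), stats_cal)
      mtt <- train_model(build_model(cfg), x_tt_n, cfg)
      rm(x_tt_n)
      res$train_time_calib[[r]] <- evaluate_model(mtt, apply_zscore(study$test, stats_cal))
      rm(mtt); gc(FALSE)
    }
  }
  lapply(stats::setNames(names(res), names(res)),
         function(m) repeat_and_aggregate(res[[m]], m))
}

#' Desk-scale training presets for the benchmark arms
#'
#' The protocol trains the calibration arms harder than the no-calibration
#' arm (which is deliberately early-stopped, mirroring repeated-training
#' protocols that cap the arm expected to fail under mismatch): the
#' calibration arms (train-time, test-time, BN freezing) train one epoch at
#' learning rate `2e-3`, the no-calibration arm one epoch at `5e-4`, and
#' fine-tuning continues from the no-calibration model for two epochs at the
#' calibration learning rate.
#'
#' @param scale Multiplies the epoch counts (the scaled-down test protocol
#'   uses `scale = 2` on half-size studies to keep the update budget
#'   comparable).
#' @return List with [classifier_config()]s `base`, `calib`, `fine_tune`.
#' @export
benchmark_presets <- function(scale = 1L) {
  list(base = classifier_config(epochs = 1L * scale, learning_rate = 5e-4),
       calib = classifier_config(epochs = 1L * scale, learning_rate = 2e-3),
       fine_tune = classifier_config(epochs = 2L * scale, learning_rate = 2e-3))
}

#' Run the full desk benchmark with per-arm presets
#'
#' Convenience wrapper executing [run_method_comparison()] in two phases --
#' the no-calibration-based arms under `presets$base` and the calibration
#' arms under `presets$calib` -- on one simulated study, with a shared
#' transfer function from the chosen calibration acquisition.
#'
#' @inheritParams run_method_comparison
#' @param presets See [benchmark_presets()].
#' @return Named list of `experiment_report`s (all eight methods).
#' @export
run_benchmark <- function(study, n_repetitions = 3L, base_seed = 100L,
                          presets = benchmark_presets(),
                          calibration = c("stable", "freehand"), tfs = NULL) {
  calibration <- match.arg(calibration)
  if (is.null(tfs)) {
    cs <- study$calib[[calibration]]
    tfs <- build_bidirectional(cs$train, cs$test)
  }
  r1 <- run_method_comparison(study, presets$base, n_repetitions, base_seed,
                              methods = c("no_calib_train_stats",
                                          "no_calib_calibrated_stats",
                                          "no_calib_test_stats",
                                          "auc_analysis", "fine_tune"),
                              tfs = tfs, config_ft = presets$fine_tune)
  r2 <- run_method_comparison(study, presets$calib, n_repetitions, base_seed,
                              methods = c("train_time_calib",
                                          "test_time_calib", "bn_freeze"),
                              tfs = tfs)
  c(r1, r2)
}
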