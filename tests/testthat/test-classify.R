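test_that("model construction honors the config contract", {
  cfg <- classifier_config(seed = 3)
  m <- build_model(cfg)
  expect_s3_class(m, "rf_classifier")
  # single finite logit for a single-channel 200 x 26 input
  x <- array(rnorm(200 * 26 * 4), c(1, 200, 26, 4))
  out <- m2mqus:::nn_forward(m$layers, m$params, x, keep_cache = FALSE)$out
  expect_length(out, 4L)
  expect_true(all(is.finite(out)))

  # identical seeds give identical initial parameters
  expect_identical(m$params, build_model(cfg)$params)
  expect_false(identical(m$params, build_model(classifier_config(seed = 4))$params))

  expect_error(build_model(classifier_config(architecture = "resnet50_adapted")),
               "not provided")
  expect_error(classifier_config(hflip_prob = 1.5), "hflip_prob")
  expect_error(classifier_config(learning_rate = 0), "learning_rate")
})

test_that("horizontal flip is an exact lateral mirror involution", {
  x <- array(rnorm(1 * 6 * 5 * 3), c(1, 6, 5, 3))
  once <- m2mqus:::flip_lateral(x, 1:3)
  expect_identical(m2mqus:::flip_lateral(once, 1:3), x)
  expect_identical(once[1, , 5:1, 2], x[1, , , 2])
})

test_that("training separates two synthetic spectral classes", {
  p <- toy_class_patches(500)
  stats <- compute_zscore_stats(p, "train")
  pn <- apply_zscore(p, stats)

  # oracle: logistic regression on band powers separates these classes
  bp <- t(apply(pn$data, 3, function(m) {
    s <- rowMeans(abs(stats::mvfft(m))^2)[1:101]
    c(sum(s[20:32]), sum(s[33:45]))
  }))
  or <- stats::glm(pn$info$class_label ~ bp[, 1] + bp[, 2], family = "binomial")
  expect_gt(mean((stats::fitted(or) > 0.5) == (pn$info$class_label == 1)), 0.99)

  cfg <- classifier_config(epochs = 4, learning_rate = 2e-3, seed = 7)
  m <- train_model(build_model(cfg), pn, cfg)
  expect_gte(utils::tail(m$history$val_accuracy, 1), 95)

  # reproducibility: identical seed and data give identical parameters
  m2 <- train_model(build_model(cfg), pn, cfg)
  expect_identical(m$params, m2$params)
  expect_identical(m$history, m2$history)

  # evaluation is deterministic and label-swap flips the AUC
  ev <- evaluate_model(m, pn)
  expect_gte(ev$accuracy, 95)
  sc <- predict_scores(m, pn)
  expect_equal(binary_auc(sc, pn$info$class_label),
               1 - binary_auc(sc, 1L - pn$info$class_label))

  one_class <- m2mqus:::subset_patches(pn, pn$info$class_label == 0)
  expect_error(train_model(build_model(cfg), one_class, cfg), "both classes")
})

test_that("evaluation metrics follow their rank-statistic definitions", {
  mk_eval <- function(scores, labels, threshold = 0.5) {
    acc <- 100 * mean((scores > threshold) == (labels == 1))
    list(acc = acc, auc = binary_auc(scores, labels))
  }
  r <- mk_eval(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(r$acc, 100)
  expect_equal(r$auc, 1)

  # constant scorer: AUC 1/2 by tie sharing
  expect_equal(binary_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)

  # 3 positives, 2 negatives, one inverted pair: brute force over all
  # positive-negative pairs gives 5/6
  sc <- c(0.9, 0.7, 0.3, 0.5, 0.1); lb <- c(1, 1, 1, 0, 0)
  brute <- mean(outer(sc[lb == 1], sc[lb == 0], ">") +
                  0.5 * outer(sc[lb == 1], sc[lb == 0], "=="))
  expect_equal(brute, 5 / 6)
  expect_equal(binary_auc(sc, lb), brute)

  expect_error(binary_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("fine-tuning updates only the unfrozen trailing layers", {
  p <- toy_class_patches(60, seed = 9)
  pn <- apply_zscore(p, compute_zscore_stats(p, "train"))
  cfg <- classifier_config(epochs = 1, seed = 5)
  m <- train_model(build_model(cfg), pn, cfg)

  ft <- fine_tune(m, pn, cfg, unfreeze = c("conv4", "fc"))
  frozen_keys <- setdiff(names(m$params),
                         c("conv4.w", "conv4.b", "fc.w", "fc.b"))
  for (key in frozen_keys) expect_identical(ft$params[[key]], m$params[[key]])
  expect_false(identical(ft$params[["fc.w"]], m$params[["fc.w"]]))

  expect_identical(fine_tune(m, pn, cfg, unfreeze = character(0)), m)
  expect_error(fine_tune(m, pn, cfg, unfreeze = "conv9"), "absent")
})

test_that("ROC threshold adaptation maximizes Youden's J", {
  yt <- m2mqus:::youden_threshold
  # perfectly separated score groups: midpoint of the gap
  expect_equal(yt(c(0.2, 0.2, 0.8, 0.8), c(0, 0, 1, 1)), 0.5)
  # a global shift of the scores shifts the chosen threshold with them
  sc <- c(0.05, 0.1, 0.2, 0.6, 0.7, 0.9)
  lb <- c(0, 0, 0, 1, 1, 1)
  expect_equal(yt(sc + 0.05, lb), yt(sc, lb) + 0.05, tolerance = 1e-12)

  # on the adaptation set itself, the chosen threshold is at least as
  # accurate as the default 0.5
  set.seed(10)
  sc2 <- stats::plogis(c(rnorm(40, 2.5), rnorm(40, 0.5)))
  lb2 <- rep(c(1, 0), each = 40)
  acc <- function(t) mean((sc2 > t) == (lb2 == 1))
  expect_gte(acc(yt(sc2, lb2)), acc(0.5))

  p <- toy_class_patches(20, seed = 3)
  one <- m2mqus:::subset_patches(p, p$info$class_label == 1)
  m <- build_model(classifier_config(seed = 1))
  expect_error(auc_threshold(m, one), "both classes")
})

test_that("batch-statistics BN depends on evaluation batch composition only", {
  p <- toy_class_patches(80, seed = 12)
  pn <- apply_zscore(p, compute_zscore_stats(p, "train"))
  cfg <- classifier_config(epochs = 1, seed = 2, eval_batch_size = 32L)
  m <- train_model(build_model(cfg), pn, cfg)

  # same batches twice: identical scores
  s1 <- predict_scores(m, pn)
  expect_identical(s1, predict_scores(m, pn))

  # different batch composition (different eval seed) changes the scores
  cfg2 <- cfg; cfg2$seed <- 99L
  s2 <- predict_scores(m, pn, cfg2)
  expect_false(isTRUE(all.equal(s1, s2)))

  # frozen-BN models ignore batch composition entirely
  cfgf <- classifier_config(epochs = 1, seed = 2, bn_mode = "frozen",
                            eval_batch_size = 32L)
  mf <- train_model(build_model(cfgf), pn, cfgf)
  f1 <- predict_scores(mf, pn)
  cfgf2 <- cfgf; cfgf2$seed <- 99L
  expect_equal(f1, predict_scores(mf, pn, cfgf2), tolerance = 1e-12)
})
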