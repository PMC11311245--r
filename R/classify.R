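#' Classifier configuration
#'
#' Training protocol for the binary RF-patch classifier: Adam optimizer,
#' binary cross-entropy on a single logit, per-batch lateral-mirror
#' (horizontal flip) augmentation, and a selectable batch-normalization
#' statistics mode.  The default `bn_mode = "batch_stats"` disables stored
#' running statistics entirely: BN layers normalize with the current batch's
#' mean/variance at both training and evaluation (affine parameters are
#' learned), so the network carries no domain statistics.  `"frozen"` keeps
#' BN normalization fixed at its initialization (the BN-freezing baseline);
#' `"running_stats"` uses accumulated training statistics at evaluation.
#'
#' @param architecture `"small_cnn"` (a fixed 4-block conv-BN-ReLU stack with
#'   global average pooling, ~17k parameters, designed for 200 x 26 RF
#'   patches), or the adapted large architectures `"resnet50_adapted"` /
#'   `"densenet201_adapted"` (accepted in the enum; not provided by this
#'   package's pure-R engine).
#' @param bn_mode BN statistics mode, see Details.
#' @param learning_rate,epochs,batch_size Adam step size, passes over the
#'   training split, and minibatch size.
#' @param hflip_prob Probability of mirroring a patch laterally during
#'   training (default 0.5).
#' @param eval_batch_size Batch size used at evaluation.  With
#'   `bn_mode = "batch_stats"` evaluation results depend on batch
#'   composition, so the evaluation order is shuffled with `seed` and the
#'   batch size is pinned for reproducibility.
#' @param seed Integer seed controlling initialization, the train/validation
#'   split, batch order, augmentation, and evaluation batch composition.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(architecture = c("small_cnn", "resnet50_adapted",
                                               "densenet201_adapted"),
                              bn_mode = c("batch_stats", "running_stats", "frozen"),
                              learning_rate = 1e-3, epochs = 3L, batch_size = 256L,
                              hflip_prob = 0.5, eval_batch_size = 256L, seed = 1L) {
  architecture <- match.arg(architecture)
  bn_mode <- match.arg(bn_mode)
  if (hflip_prob < 0 || hflip_prob > 1) stop("`hflip_prob` must be in [0, 1]")
  if (learning_rate <= 0) stop("`learning_rate` must be > 0")
  structure(list(architecture = architecture, bn_mode = bn_mode,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), hflip_prob = hflip_prob,
                 eval_batch_size = as.integer(eval_batch_size),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

small_cnn_layers <- function(input_h = 200L, input_w = 26L) {
  list(conv_layer("conv1", 1L, 16L, 9L, 3L, 4L, 2L), bnrelu_layer("bn1", 16L),
       conv_layer("conv2", 16L, 16L, 3L, 3L, 2L, 2L), bnrelu_layer("bn2", 16L),
       conv_layer("conv3", 16L, 32L, 3L, 3L, 2L, 1L), bnrelu_layer("bn3", 32L),
       conv_layer("conv4", 32L, 32L, 3L, 3L, 2L, 1L), bnrelu_layer("bn4", 32L),
       gap_layer("gap"), fc_layer("fc", 32L))
}

#' Build an initialized classifier
#'
#' The model accepts single-channel `patch_axial x patch_lateral` RF input
#' and emits one logit (sigmoid probability of class 1).  Initialization is
#' He-normal under `config$seed`, so identical seeds give identical initial
#' parameters.
#'
#' @param config A [classifier_config()].
#' @param input_h,input_w Patch dimensions (axial samples, scan lines).
#' @return An object of class `rf_classifier`.
#' @export
build_model <- function(config = classifier_config(), input_h = 200L, input_w = 26L) {
  stopifnot(inherits(config, "classifier_config"))
  if (config$architecture != "small_cnn")
    stop("architecture '", config$architecture, "' is not provided by the pure-R ",
         "engine; use 'small_cnn'")
  layers <- small_cnn_layers(input_h, input_w)
  params <- with_seed(config$seed, init_params(layers))
  structure(list(architecture = config$architecture, layers = layers,
                 params = params, config = config,
                 bn_stats = new.env(parent = emptyenv()),
                 history = NULL),
            class = "rf_classifier")
}

#' @export
print.rf_classifier <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<rf_classifier> %s, %d parameters, bn_mode=%s%s\n",
              x$architecture, np, x$config$bn_mode,
              if (is.null(x$history)) " (untrained)" else
                sprintf(", %d epochs trained", nrow(x$history))))
  invisible(x)
}

flip_lateral <- function(x4, idx) {
  w <- dim(x4)[3L]
  x4[, , , idx] <- x4[, , w:1, idx, drop = FALSE]
  x4
}

#' Train the classifier on labeled, normalized patches
#'
#' Splits the patches 4:1 into training and validation sets (stratified over
#' class and depth zone), then optimizes binary cross-entropy with Adam,
#' mirroring each patch laterally with probability `hflip_prob` per batch.
#' Normalization statistics are the caller's responsibility: the patches
#' should already be z-scored with the statistics the experiment protocol
#' prescribes.  With a fixed `config$seed` and fixed input order, training is
#' reproducible.
#'
#' @param model An `rf_classifier` from [build_model()].
#' @param patches A `patch_set` with class labels (both classes present).
#' @param config A [classifier_config()]; defaults to the model's.
#' @param trainable Character vector of parameter names to update (default
#'   all) -- used by [fine_tune()].
#' @param split_ratio Train : validation parts (default 4:1).
#' @return The trained `rf_classifier`, with `history` (per-epoch training
#'   loss and validation accuracy).
#' @export
train_model <- function(model, patches, config = model$config,
                        trainable = names(model$params), split_ratio = c(4, 1)) {
  stopifnot(inherits(model, "rf_classifier"), inherits(patches, "patch_set"))
  labels <- patches$info$class_label
  if (any(is.na(labels))) stop("all patches must carry a class label")
  if (length(unique(labels)) < 2L) stop("training requires both classes")
  tr_idx <- split_indices(patches$info, split_ratio, derive_seed(config$seed, 1L))
  val_idx <- setdiff(seq_len(n_patches(patches)), tr_idx)
  ytr <- labels[tr_idx]
  ntr <- length(ytr)
  pdim <- dim(patches$data)[1:2]
  if (config$bn_mode == "frozen" && !length(ls(model$bn_stats))) {
    # freeze BN normalization at the activation statistics of a warmup batch
    # (the stand-in for a pretrained model's stored statistics)
    wb <- with_seed(derive_seed(config$seed, 4L),
                    sample(tr_idx, min(512L, ntr)))
    xw <- patches$data[, , wb, drop = FALSE]
    dim(xw) <- c(1L, pdim, length(wb))
    freeze_bn_stats(model, xw)
  }
  layers <- model$layers; params <- model$params
  opt <- adam_init(params)
  hist <- data.frame(epoch = integer(0), loss = numeric(0), val_accuracy = numeric(0))
  with_seed(derive_seed(config$seed, 2L), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(ntr)
      losses <- numeric(0)
      step <- 0L
      for (b in seq(1L, ntr, by = config$batch_size)) {
        step <- step + 1L
        if (step %% 10L == 0L) gc(FALSE)   # cap transient allocation growth
        bidx <- ord[b:min(b + config$batch_size - 1L, ntr)]
        if (length(bidx) < 2L) next
        xb <- patches$data[, , tr_idx[bidx], drop = FALSE]
        dim(xb) <- c(1L, pdim, length(bidx))
        fl <- which(stats::runif(length(bidx)) < config$hflip_prob)
        if (length(fl)) xb <- flip_lateral(xb, fl)
        fw <- nn_forward(layers, params, xb, bn_mode = config$bn_mode,
                         training = TRUE, stats_env = model$bn_stats)
        lo <- bce_with_logits(fw$out, ytr[bidx])
        grads <- nn_backward(layers, params, fw$cache, lo$dz)
        st <- adam_step(params, grads, opt, config$learning_rate, trainable)
        params <- st$params; opt <- st$state
        losses <- c(losses, lo$loss)
      }
      model$params <- params
      val <- evaluate_model(model, subset_patches(patches, val_idx))
      gc(FALSE)
      hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                     val_accuracy = val$accuracy))
    }
  })
  model$params <- params
  model$history <- hist
  model$config <- config
  model
}

#' Classifier scores for a patch set
#'
#' Sigmoid probabilities of class 1, evaluated in pinned-size batches.  With
#' `bn_mode = "batch_stats"` the batch composition matters, so the order is
#' shuffled under the configured seed and scores are returned in the original
#' patch order.
#'
#' @inheritParams train_model
#' @return Numeric vector of per-patch scores in `[0, 1]`.
#' @export
predict_scores <- function(model, patches, config = model$config) {
  stopifnot(inherits(model, "rf_classifier"), inherits(patches, "patch_set"))
  n <- n_patches(patches)
  if (!n) stop("no patches to score")
  pdim <- dim(patches$data)[1:2]
  ord <- with_seed(derive_seed(config$seed, 3L), sample.int(n))
  scores <- numeric(n)
  for (b in seq(1L, n, by = config$eval_batch_size)) {
    bidx <- ord[b:min(b + config$eval_batch_size - 1L, n)]
    xb <- patches$data[, , bidx, drop = FALSE]
    dim(xb) <- c(1L, pdim, length(bidx))
    fw <- nn_forward(model$layers, model$params, xb,
                     bn_mode = config$bn_mode, training = FALSE,
                     keep_cache = FALSE, stats_env = model$bn_stats)
    scores[bidx] <- stats::plogis(fw$out)
  }
  scores
}

#' Patchwise evaluation: accuracy and AUC
#'
#' Accuracy is the percentage of patches whose thresholded score matches the
#' label; AUC is the area under the ROC curve computed by the rank statistic
#' (equivalent to the normalized Mann-Whitney U, ties shared equally).
#'
#' @inheritParams train_model
#' @param threshold Decision threshold on the sigmoid score (default 0.5; see
#'   [auc_threshold()] for the adapted-threshold baseline).
#' @return List of class `eval_result`: `accuracy` (percent), `auc`,
#'   `n_patches`, `per_class` counts, `threshold`.
#' @export
evaluate_model <- function(model, patches, threshold = 0.5) {
  labels <- patches$info$class_label
  if (any(is.na(labels))) stop("evaluation requires labeled patches")
  eval_from_scores(predict_scores(model, patches), labels, threshold)
}

eval_from_scores <- function(scores, labels, threshold) {
  acc <- 100 * mean((scores > threshold) == (labels == 1L))
  auc <- if (length(unique(labels)) == 2L) binary_auc(scores, labels) else NA_real_
  structure(list(accuracy = acc, auc = auc, n_patches = length(labels),
                 per_class = table(labels), threshold = threshold),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%, AUC %.4f (n = %d, threshold %.3f)\n",
              x$accuracy, x$auc, x$n_patches, x$threshold))
  invisible(x)
}

#' Rank-statistic AUC
#'
#' @param scores Numeric scores (higher = more class-1).
#' @param labels 0/1 labels.
#' @return Area under the ROC curve in `[0, 1]`.
#' @export
binary_auc <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fine-tune trailing layers on adaptation data
#'
#' Continues training with only the named trailing layers unfrozen (for
#' `small_cnn`: the last convolution and the linear head); every other
#' parameter is bit-identical before and after.
#'
#' @inheritParams train_model
#' @param unfreeze Layer names whose parameters are updated.
#' @return The fine-tuned `rf_classifier`.
#' @export
fine_tune <- function(model, patches, config = model$config,
                      unfreeze = c("conv4", "fc")) {
  layer_names <- unique(vapply(model$layers, `[[`, character(1), "name"))
  missing <- setdiff(unfreeze, layer_names)
  if (length(missing))
    stop("unfreeze names absent from the model: ", paste(missing, collapse = ", "))
  if (!length(unfreeze)) return(model)
  trainable <- names(model$params)[
    sub("\\.[^.]+$", "", names(model$params)) %in% unfreeze]
  train_model(model, patches, config, trainable = trainable)
}

#' Adapted decision threshold from ROC analysis
#'
#' Chooses the threshold on the sigmoid output that maximizes Youden's J
#' (sensitivity + specificity - 1) over the adaptation set's ROC curve,
#' for use in [evaluate_model()].  Candidate thresholds are midpoints
#' between adjacent distinct scores; among ties the candidate closest to the
#' center of the maximizing run is returned, so perfectly separated score
#' groups yield the midpoint of the gap.
#'
#' @param model An `rf_classifier`.
#' @param patches Labeled adaptation `patch_set` (both classes present).
#' @return The selected threshold (numeric scalar).
#' @export
auc_threshold <- function(model, patches) {
  labels <- patches$info$class_label
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop("adaptation set must contain both classes")
  scores <- predict_scores(model, patches)
  youden_threshold(scores, labels)
}

youden_threshold <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- if (length(s) > 1L) (head(s, -1L) + tail(s, -1L)) / 2 else s
  j <- vapply(cand, function(t) {
    mean(scores[labels == 1L] > t) - mean(scores[labels == 0L] > t)
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  cand[best[ceiling(length(best) / 2)]]
}
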