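# Minimal feed-forward CNN machinery: channels-first activations
# [C, H, W, N], convolutions via im2col + BLAS GEMM, batch normalization
# with selectable statistics mode, Adam updates.  Only what the RF-patch
# classifier needs; not a general deep-learning framework.

conv_layer <- function(name, c_in, c_out, kh, kw, sh, sw) {
  list(type = "conv", name = name, c_in = c_in, c_out = c_out,
       kh = kh, kw = kw, sh = sh, sw = sw)
}
bnrelu_layer <- function(name, channels)
  list(type = "bnrelu", name = name, channels = channels)
gap_layer <- function(name) list(type = "gap", name = name)
fc_layer <- function(name, d_in) list(type = "fc", name = name, d_in = d_in)

# He-normal initialization for conv/fc weights; BN affine starts at identity.
init_params <- function(layers) {
  params <- list()
  for (ly in layers) {
    if (ly$type == "conv") {
      fan_in <- ly$c_in * ly$kh * ly$kw
      params[[paste0(ly$name, ".w")]] <-
        array(stats::rnorm(fan_in * ly$c_out, sd = sqrt(2 / fan_in)),
              c(ly$c_in, ly$kh, ly$kw, ly$c_out))
      params[[paste0(ly$name, ".b")]] <- numeric(ly$c_out)
    } else if (ly$type == "bnrelu") {
      params[[paste0(ly$name, ".gamma")]] <- rep(1, ly$channels)
      params[[paste0(ly$name, ".beta")]] <- rep(0, ly$channels)
    } else if (ly$type == "fc") {
      params[[paste0(ly$name, ".w")]] <- stats::rnorm(ly$d_in, sd = sqrt(2 / ly$d_in))
      params[[paste0(ly$name, ".b")]] <- 0
    }
  }
  params
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Forward pass.  `x` is [C, H, W, N].  BN statistics source:
#   batch_stats  - per-batch mean/var at train AND eval (no stored stats);
#   frozen       - fixed (0, 1) normalization throughout, affine learned;
#   running_stats- batch stats while training (accumulated with momentum
#                  into `stats_env`), stored stats at evaluation.
nn_forward <- function(layers, params, x, bn_mode = "batch_stats",
                       training = TRUE, keep_cache = TRUE, stats_env = NULL) {
  cache <- if (keep_cache) vector("list", length(layers)) else NULL
  for (li in seq_along(layers)) {
    ly <- layers[[li]]
    if (ly$type == "conv") {
      d <- dim(x)
      y <- conv_fwd(x, params[[paste0(ly$name, ".w")]],
                    params[[paste0(ly$name, ".b")]],
                    d[1L], d[2L], d[3L], d[4L], ly$kh, ly$kw, ly$sh, ly$sw,
                    ly$c_out)
      outH <- (d[2L] - ly$kh) %/% ly$sh + 1L
      outW <- (d[3L] - ly$kw) %/% ly$sw + 1L
      dim(y) <- c(ly$c_out, outH, outW, d[4L])
      if (keep_cache) cache[[li]] <- list(x_in = x, dim_in = d)
      x <- y
    } else if (ly$type == "bnrelu") {
      d <- dim(x)
      nch <- d[1L]
      fixed <- FALSE
      mu <- numeric(nch); va <- rep(1, nch)
      if (bn_mode == "frozen") {
        st <- if (!is.null(stats_env)) stats_env[[ly$name]]
        if (!is.null(st)) { mu <- st$mu; va <- st$va }
        fixed <- TRUE
      } else if (bn_mode == "running_stats" && !training) {
        st <- stats_env[[ly$name]]
        if (is.null(st)) stop("no stored BN statistics for layer ", ly$name)
        mu <- st$mu; va <- st$va; fixed <- TRUE
      }
      fw <- bn_relu_fwd(x, nch, params[[paste0(ly$name, ".gamma")]],
                        params[[paste0(ly$name, ".beta")]], mu, va, fixed)
      if (bn_mode == "running_stats" && training && !is.null(stats_env)) {
        st <- stats_env[[ly$name]]
        if (is.null(st)) st <- list(mu = fw$mu * 0, va = fw$va * 0 + 1)
        stats_env[[ly$name]] <- list(
          mu = (1 - BN_MOMENTUM) * st$mu + BN_MOMENTUM * fw$mu,
          va = (1 - BN_MOMENTUM) * st$va + BN_MOMENTUM * fw$va)
      }
      y <- fw$y
      dim(y) <- d
      if (keep_cache)
        cache[[li]] <- list(x_in = x, y = y, mu = fw$mu, inv = fw$inv,
                            dim = d, fixed = fixed)
      x <- y
    } else if (ly$type == "gap") {
      d <- dim(x)
      xm <- x
      dim(xm) <- c(d[1L], d[2L] * d[3L], d[4L])
      y <- apply(xm, 3L, rowMeans)
      if (is.null(dim(y))) y <- matrix(y, d[1L], d[4L])
      if (keep_cache) cache[[li]] <- list(dim = d)
      x <- y
    } else if (ly$type == "fc") {
      w <- params[[paste0(ly$name, ".w")]]
      z <- drop(crossprod(x, w)) + params[[paste0(ly$name, ".b")]]
      if (keep_cache) cache[[li]] <- list(x = x)
      x <- z
    }
  }
  list(out = x, cache = cache)
}

# Backward pass from d(loss)/d(logits).  Returns named gradient list.
nn_backward <- function(layers, params, cache, dout) {
  grads <- list()
  g <- dout
  for (li in rev(seq_along(layers))) {
    ly <- layers[[li]]
    cc <- cache[[li]]
    if (ly$type == "fc") {
      x <- cc$x                          # [C, N]
      grads[[paste0(ly$name, ".w")]] <- drop(x %*% g)
      grads[[paste0(ly$name, ".b")]] <- sum(g)
      g <- outer(params[[paste0(ly$name, ".w")]], g)   # [C, N]
    } else if (ly$type == "gap") {
      d <- cc$dim
      hw <- d[2L] * d[3L]
      gm <- matrix(g, d[1L], d[4L]) / hw
      g <- array(apply(gm, 2L, rep, times = hw), d)
    } else if (ly$type == "bnrelu") {
      d <- cc$dim
      bw <- bn_relu_bwd(g, cc$x_in, cc$y, cc$mu, cc$inv,
                        params[[paste0(ly$name, ".gamma")]], d[1L], cc$fixed)
      grads[[paste0(ly$name, ".gamma")]] <- bw$dgamma
      grads[[paste0(ly$name, ".beta")]] <- bw$dbeta
      g <- bw$gx
      dim(g) <- d
    } else if (ly$type == "conv") {
      d <- cc$dim_in
      wkey <- paste0(ly$name, ".w")
      bw <- conv_bwd(g, cc$x_in, params[[wkey]],
                     d[1L], d[2L], d[3L], d[4L], ly$kh, ly$kw, ly$sh, ly$sw,
                     ly$c_out)
      grads[[wkey]] <- array(bw$dw, dim(params[[wkey]]))
      grads[[paste0(ly$name, ".b")]] <- bw$db
      g <- bw$dx
      dim(g) <- d
    }
  }
  grads
}

# One forward pass with per-batch statistics, storing each BN layer's batch
# mean/variance into the model's stats environment; those become the fixed
# normalization of bn_mode = "frozen".
freeze_bn_stats <- function(model, x) {
  layers <- model$layers
  params <- model$params
  for (li in seq_along(layers)) {
    ly <- layers[[li]]
    if (ly$type == "conv") {
      d <- dim(x)
      x <- conv_fwd(x, params[[paste0(ly$name, ".w")]],
                    params[[paste0(ly$name, ".b")]],
                    d[1L], d[2L], d[3L], d[4L], ly$kh, ly$kw, ly$sh, ly$sw,
                    ly$c_out)
      dim(x) <- c(ly$c_out, (d[2L] - ly$kh) %/% ly$sh + 1L,
                  (d[3L] - ly$kw) %/% ly$sw + 1L, d[4L])
    } else if (ly$type == "bnrelu") {
      d <- dim(x)
      fw <- bn_relu_fwd(x, d[1L], params[[paste0(ly$name, ".gamma")]],
                        params[[paste0(ly$name, ".beta")]],
                        numeric(d[1L]), numeric(d[1L]), FALSE)
      model$bn_stats[[ly$name]] <- list(mu = fw$mu, va = fw$va)
      x <- fw$y
      dim(x) <- d
    } else break   # statistics collected for every BN layer by now
  }
  invisible(model)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, trainable = names(params),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (key in names(grads)) {
    if (!(key %in% trainable)) next
    gr <- grads[[key]]
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * gr
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * gr^2
    mhat <- state$m[[key]] / (1 - beta1^state$t)
    vhat <- state$v[[key]] / (1 - beta2^state$t)
    params[[key]] <- params[[key]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Numerically stable binary cross-entropy with logits; returns loss and
# d(loss)/d(logit) (mean reduction).
bce_with_logits <- function(z, y) {
  loss <- mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
  p <- stats::plogis(z)
  list(loss = loss, dz = (p - y) / length(z))
}
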