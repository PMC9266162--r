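# Three-branch convolutional classifier. Each feature branch (PSSM, DSSP,
# HMM) passes its n x m window through three stride-1 valid 1-D convolutions
# along the window axis (kernels 5/3/3, filters 64/32/16, ReLU), then layer
# normalization and branch-specific dropout; the flattened branch outputs are
# concatenated and classified by a ReLU dense head 256/128/64 with a single
# sigmoid output unit. Trained by SGD with momentum on binary cross-entropy.
# Forward and backward passes are implemented directly with matrix algebra
# (im2col convolutions), so training is fully deterministic given a seed.

#' Rectified linear activation
#' @param f Numeric input (any shape).
#' @return `max(0, f)` elementwise.
#' @export
relu <- function(f) pmax(f, 0)

#' Logistic sigmoid activation
#' @param f Numeric input (any shape).
#' @return `1 / (1 + exp(-f))` elementwise.
#' @export
sigmoid <- function(f) 1 / (1 + exp(-f))

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood of Bernoulli labels under predicted scores.
#' Scores are clipped away from 0 and 1 by `clip` so the loss is always
#' finite.
#'
#' @param labels 0/1 vector.
#' @param scores Predicted probabilities, same length.
#' @param clip Clipping margin (default 1e-7).
#' @return Scalar loss.
#' @export
bce_loss <- function(labels, scores, clip = 1e-7) {
  stopifnot(length(labels) == length(scores))
  p <- pmin(pmax(scores, clip), 1 - clip)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Model configuration
#'
#' Defaults reproduce the published architecture verbatim: branch order
#' (pssm, dssp, hmm) for sub-architectures 1-3, convolution kernels (5, 3, 3)
#' with (64, 32, 16) filters at stride 1 and no padding, branch dropout
#' ratios (0.1, 0.3, 0.2), dense head (256, 128, 64, 1), ReLU hidden
#' activations and a sigmoid output, window length 19. Training
#' hyperparameters are not part of the published architecture; the defaults
#' (SGD, learning rate 0.02 decayed by 0.90 per epoch, momentum 0.9, batch
#' size 256, 28 epochs, weight decay 0.03, positive bias initialization
#' with centered inputs) were chosen for reliable convergence of this
#' parameter-heavy network in the small-sample cross-validation regime.
#'
#' @param window Window length `n` (odd, >= 9 for the default kernel stack).
#' @param branches Which feature branches to build, a subset of
#'   `c("pssm", "dssp", "hmm")` in sub-architecture order.
#' @param kernels,filters Convolution kernel sizes and filter counts, shared
#'   across branches.
#' @param dropout Named per-branch dropout ratios.
#' @param dense Dense-head widths; the last entry must be 1.
#' @param feature_dims Named per-branch input feature dimensions.
#' @param lr,momentum,batch_size,epochs,patience SGD settings.
#' @param weight_decay L2 penalty coefficient applied to every weight matrix
#'   (not biases or layer-norm affine parameters) during training.
#' @param lr_decay Per-epoch multiplicative learning-rate decay (1 = constant).
#' @param lr_warmup Epochs of linear learning-rate ramp-up before the decay
#'   starts; stabilizes the first updates against bad initial minibatches.
#' @param bias_init Initial value of all convolution and dense biases. A
#'   small positive value keeps the ReLU units active at initialization
#'   (inputs are centered), so optimization starts close to the linear
#'   regime.
#' @param center_inputs Subtract 0.5 from the (0-1 scaled) input features
#'   before the first convolution. A pure reparameterization of the first
#'   conv bias that improves SGD conditioning; the function class is
#'   unchanged.
#' @param clip Loss clipping margin.
#' @param layernorm_eps Layer-normalization variance floor.
#' @param threshold Default classification threshold on the sigmoid score.
#' @return An object of class `model_config`.
#' @export
model_config <- function(window = 19L,
                         branches = c("pssm", "dssp", "hmm"),
                         kernels = c(5L, 3L, 3L),
                         filters = c(64L, 32L, 16L),
                         dropout = c(pssm = 0.1, dssp = 0.3, hmm = 0.2),
                         dense = c(256L, 128L, 64L, 1L),
                         feature_dims = c(pssm = 20L, dssp = 14L, hmm = 20L),
                         lr = 0.02, momentum = 0.9,
                         batch_size = 256L, epochs = 28L, patience = 15L,
                         weight_decay = 0.03, center_inputs = TRUE,
                         lr_decay = 0.90, lr_warmup = 3L, bias_init = 0.1,
                         clip = 1e-7, layernorm_eps = 1e-5,
                         threshold = 0.5) {
  window <- as.integer(window)
  branches <- match.arg(branches, c("pssm", "dssp", "hmm"),
                        several.ok = TRUE)
  if (window %% 2L == 0L) stop("window length must be odd (2a + 1)")
  if (length(kernels) != length(filters))
    stop("kernels and filters must have the same length")
  if (dense[[length(dense)]] != 1L)
    stop("the final dense layer must have exactly 1 unit")
  ext <- window
  for (k in kernels) ext <- ext - k + 1L
  if (ext < 1L)
    stop("window length ", window, " is too small for the kernel stack (",
         paste(kernels, collapse = ","), "): need n >= ",
         sum(kernels) - length(kernels) + 1L)
  cfg <- structure(list(
    window = window, branches = branches,
    kernels = as.integer(kernels), filters = as.integer(filters),
    dropout = dropout, dense = as.integer(dense),
    feature_dims = feature_dims,
    lr = lr, momentum = momentum, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), patience = as.integer(patience),
    weight_decay = weight_decay, center_inputs = isTRUE(center_inputs),
    lr_decay = lr_decay, lr_warmup = as.integer(lr_warmup),
    bias_init = bias_init,
    clip = clip, layernorm_eps = layernorm_eps, threshold = threshold),
    class = "model_config")
  cfg
}

#' Convolution output lengths for a configuration
#'
#' Valid stride-1 convolution shrinks the window by `k - 1` per layer:
#' lengths `n - k1 + 1`, then successively smaller.
#' @param config A [model_config()].
#' @return Integer vector, one extent per convolution layer.
#' @export
conv_extents <- function(config) {
  ext <- integer(0)
  n <- config$window
  for (k in config$kernels) {
    n <- n - k + 1L
    ext <- c(ext, n)
  }
  ext
}

#' Width of the concatenated pre-dense feature vector
#'
#' Each branch contributes (final conv extent) x (final filter count); the
#' default three-branch model at window 19 gives 3 x 11 x 16 = 528.
#' @param config A [model_config()].
#' @return Integer width.
#' @export
concat_width <- function(config) {
  ext <- conv_extents(config)
  length(config$branches) * ext[[length(ext)]] *
    config$filters[[length(config$filters)]]
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build a model with seeded parameter initialization
#'
#' @param config A [model_config()].
#' @param seed Integer seed; two builds with the same seed have identical
#'   initial parameters.
#' @return An object of class `ppisite_model` (flat named parameter list plus
#'   the configuration).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  set.seed(seed)
  ext <- conv_extents(config)
  nl <- length(config$kernels)
  b0 <- config$bias_init %||% 0
  params <- list()
  for (br in config$branches) {
    cin <- config$feature_dims[[br]]
    for (l in seq_len(nl)) {
      k <- config$kernels[[l]]
      cout <- config$filters[[l]]
      params[[paste0(br, ".conv", l, ".W")]] <-
        glorot(k * cin, cout, k * cin, k * cout)
      params[[paste0(br, ".conv", l, ".b")]] <- rep(b0, cout)
      cin <- cout
    }
    D <- ext[[nl]] * config$filters[[nl]]
    params[[paste0(br, ".ln.gamma")]] <- rep(1, D)
    params[[paste0(br, ".ln.beta")]] <- numeric(D)
  }
  fin <- concat_width(config)
  for (l in seq_along(config$dense)) {
    fout <- config$dense[[l]]
    params[[paste0("dense", l, ".W")]] <- glorot(fin, fout, fin, fout)
    params[[paste0("dense", l, ".b")]] <- rep(b0, fout)
    fin <- fout
  }
  structure(list(config = config, params = params, seed = seed),
            class = "ppisite_model")
}

#' Number of trainable parameters
#' @param model A `ppisite_model`.
#' @return Integer count.
#' @export
n_params <- function(model) sum(vapply(model$params, length, 0L))

# Convolutions work on a 2-D layout: the (B, n, m) window tensor is viewed as
# a (B*n, m) matrix whose row index is sample + (position-1)*B (the natural
# column-major flattening, so the view is free). A valid stride-1 convolution
# is then a sum over kernel taps j of shifted contiguous row blocks of
# X %*% W_j, which keeps everything in BLAS-friendly 2-D operations.
conv_fwd <- function(Xmat, B, n, m, W, b, k) {
  list(Z = .conv_fwd_cpp(Xmat, W, b, k, B),
       Xmat = Xmat, B = B, n = n, m = m, on = n - k + 1L, k = k)
}

conv_bwd <- function(dZ, fw, W, need_dX = TRUE) {
  .conv_bwd_cpp(dZ, fw$Xmat, W, fw$k, fw$B, need_dX)
}

ln_fwd <- function(X, gamma, beta, eps) .ln_fwd_cpp(X, gamma, beta, eps)

ln_bwd <- function(dY, fw, gamma) .ln_bwd_cpp(dY, fw$xhat, fw$inv, gamma)

#' Forward pass
#'
#' @param model A `ppisite_model`.
#' @param batch A `window_batch` whose window length matches the model.
#' @param training Apply dropout (TRUE) or run inference (FALSE, dropout
#'   inert).
#' @return List with `scores` (strictly inside (0, 1)) and, when
#'   `training = TRUE` downstream gradients are needed, the full `cache`.
#' @export
model_forward <- function(model, batch, training = FALSE) {
  cfg <- model$config
  p <- model$params
  if (batch$n != cfg$window)
    stop("window length mismatch: batch ", batch$n, ", model ", cfg$window)
  B <- dim(batch$pssm)[[1]]
  nl <- length(cfg$kernels)
  cache <- list(B = B, branches = list())
  flat <- list()
  for (br in cfg$branches) {
    X <- batch[[br]]
    bc <- list(convs = list())
    Amat <- X
    n_cur <- dim(X)[[2]]
    m_cur <- dim(X)[[3]]
    dim(Amat) <- c(B * n_cur, m_cur)
    if (cfg$center_inputs %||% FALSE) Amat <- Amat - 0.5
    for (l in seq_len(nl)) {
      fw <- conv_fwd(Amat, B, n_cur, m_cur,
                     p[[paste0(br, ".conv", l, ".W")]],
                     p[[paste0(br, ".conv", l, ".b")]], cfg$kernels[[l]])
      Amat <- .relu_cpp(fw$Z)
      bc$convs[[l]] <- list(fw = fw, act = Amat)
      n_cur <- fw$on
      m_cur <- ncol(Amat)
    }
    D <- n_cur * m_cur
    Fl <- Amat
    dim(Fl) <- c(B, D)
    ln <- ln_fwd(Fl, p[[paste0(br, ".ln.gamma")]],
                 p[[paste0(br, ".ln.beta")]], cfg$layernorm_eps)
    H <- ln$Y
    if (training && cfg$dropout[[br]] > 0) {
      keep <- 1 - cfg$dropout[[br]]
      mask <- matrix((stats::runif(length(H)) < keep) / keep, nrow(H), ncol(H))
      H <- H * mask
      bc$drop_mask <- mask
    }
    bc$ln <- ln
    bc$final_dim <- c(n_cur, m_cur)
    cache$branches[[br]] <- bc
    flat[[br]] <- H
  }
  C <- do.call(cbind, flat[cfg$branches])
  cache$C <- C
  H <- C
  dl <- length(cfg$dense)
  cache$dense <- list()
  for (l in seq_len(dl)) {
    Z <- H %*% p[[paste0("dense", l, ".W")]]
    Z <- Z + rep(p[[paste0("dense", l, ".b")]], each = nrow(Z))
    cache$dense[[l]] <- list(input = H, Z = Z)
    H <- if (l < dl) relu(Z) else sigmoid(Z)
    cache$dense[[l]]$out <- H
  }
  scores <- pmin(pmax(as.vector(H), 1e-12), 1 - 1e-12)
  list(scores = scores, cache = cache)
}

model_backward <- function(model, batch, fwd, labels) {
  cfg <- model$config
  p <- model$params
  cache <- fwd$cache
  B <- cache$B
  grads <- list()
  dl <- length(cfg$dense)
  # d(BCE)/d(logit) for the sigmoid output unit
  dZ <- matrix((fwd$scores - labels) / B, B, 1)
  for (l in rev(seq_len(dl))) {
    dc <- cache$dense[[l]]
    if (l < dl) dZ <- dZ * (dc$Z > 0)
    grads[[paste0("dense", l, ".W")]] <- crossprod(dc$input, dZ)
    grads[[paste0("dense", l, ".b")]] <- colSums(dZ)
    dZ <- dZ %*% t(p[[paste0("dense", l, ".W")]])
  }
  dC <- dZ
  off <- 0L
  nl <- length(cfg$kernels)
  for (br in cfg$branches) {
    bc <- cache$branches[[br]]
    D <- prod(bc$final_dim)
    dH <- dC[, off + seq_len(D), drop = FALSE]
    off <- off + D
    if (!is.null(bc$drop_mask)) dH <- dH * bc$drop_mask
    lnb <- ln_bwd(dH, bc$ln, p[[paste0(br, ".ln.gamma")]])
    grads[[paste0(br, ".ln.gamma")]] <- lnb$dgamma
    grads[[paste0(br, ".ln.beta")]] <- lnb$dbeta
    dA <- lnb$dX
    for (l in rev(seq_len(nl))) {
      cc <- bc$convs[[l]]
      dim(dA) <- dim(cc$act)
      dZc <- .relu_bwd_cpp(dA, cc$act)
      cb <- conv_bwd(dZc, cc$fw, p[[paste0(br, ".conv", l, ".W")]],
                     need_dX = l > 1L)
      grads[[paste0(br, ".conv", l, ".W")]] <- cb$dW
      grads[[paste0(br, ".conv", l, ".b")]] <- cb$db
      dA <- cb$dXmat
    }
  }
  grads
}

#' Train a model by SGD with momentum
#'
#' Minimizes binary cross-entropy over shuffled mini-batches. Fully
#' deterministic given `seed` (which drives shuffling, dropout masks and
#' nothing else). If a labelled `validation` batch is supplied, training
#' tracks validation AUPRC each epoch and stops early after `patience`
#' epochs without improvement, returning the best parameters.
#'
#' @param model A freshly built (or previously trained) `ppisite_model`.
#' @param batch Labelled `window_batch` of training windows.
#' @param validation Optional labelled `window_batch`.
#' @param epochs,lr,momentum,batch_size,patience Override the corresponding
#'   configuration defaults.
#' @param seed RNG seed for shuffling and dropout.
#' @param verbose Print an epoch log to stderr.
#' @return List with the trained `model` and a `history` data frame (epoch,
#'   mean training loss, validation AUPRC when available).
#' @export
train_model <- function(model, batch, validation = NULL,
                        epochs = NULL, lr = NULL, momentum = NULL,
                        batch_size = NULL, patience = NULL,
                        weight_decay = NULL, lr_decay = NULL,
                        seed = 1L, verbose = FALSE) {
  cfg <- model$config
  if (is.null(batch$labels)) stop("training requires a labelled window batch")
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  lr <- if (is.null(lr)) cfg$lr else lr
  momentum <- if (is.null(momentum)) cfg$momentum else momentum
  batch_size <- if (is.null(batch_size)) cfg$batch_size else as.integer(batch_size)
  patience <- if (is.null(patience)) cfg$patience else as.integer(patience)
  weight_decay <- if (is.null(weight_decay)) cfg$weight_decay %||% 0 else weight_decay
  lr_decay <- if (is.null(lr_decay)) cfg$lr_decay %||% 1 else lr_decay
  lr_warmup <- cfg$lr_warmup %||% 0L
  decayed <- grepl("\\.W$", names(model$params))
  names(decayed) <- names(model$params)
  set.seed(seed)
  y <- batch$labels
  N <- length(y)
  vel <- lapply(model$params, function(w) array(0, dim(w) %||% length(w)))
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_auprc = numeric(0))
  best <- list(metric = -Inf, params = NULL, epoch = 0L)
  for (epoch in seq_len(epochs)) {
    lr_e <- lr * min(1, epoch / max(1L, lr_warmup)) *
      lr_decay^(max(0L, epoch - max(1L, lr_warmup)))
    ord <- sample.int(N)
    tot_loss <- 0
    for (start in seq(1L, N, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, N)]
      sub <- subset_windows(batch, idx)
      fwd <- model_forward(model, sub, training = TRUE)
      loss <- bce_loss(y[idx], fwd$scores, cfg$clip)
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at epoch ", epoch)
      tot_loss <- tot_loss + loss * length(idx)
      grads <- model_backward(model, sub, fwd, y[idx])
      for (nm in names(grads)) {
        g <- grads[[nm]]
        if (weight_decay > 0 && decayed[[nm]])
          g <- g + weight_decay * model$params[[nm]]
        vel[[nm]] <- momentum * vel[[nm]] - lr_e * g
        model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
      }
    }
    val_auprc <- NA_real_
    if (!is.null(validation)) {
      vs <- predict_model(model, validation)
      val_auprc <- compute_metrics(validation$labels, vs)$auprc
      if (!is.na(val_auprc) && val_auprc > best$metric) {
        best <- list(metric = val_auprc, params = model$params, epoch = epoch)
      } else if (epoch - best$epoch >= patience) {
        history <- rbind(history, data.frame(
          epoch = epoch, loss = tot_loss / N, val_auprc = val_auprc))
        break
      }
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = tot_loss / N, val_auprc = val_auprc))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f%s", epoch, tot_loss / N,
                      if (is.na(val_auprc)) "" else
                        sprintf("  val AUPRC %.4f", val_auprc)))
  }
  if (!is.null(validation) && !is.null(best$params))
    model$params <- best$params
  list(model = model, history = history)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict per-residue binding-site scores
#'
#' Inference forward pass (dropout inert), in chunks.
#' @param model A trained `ppisite_model`.
#' @param batch A `window_batch`.
#' @param chunk_size Samples per forward chunk.
#' @return Numeric vector of scores strictly inside (0, 1), one per residue.
#' @export
predict_model <- function(model, batch, chunk_size = 2048L) {
  N <- dim(batch$pssm)[[1]]
  out <- numeric(N)
  for (start in seq(1L, N, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, N)
    out[idx] <- model_forward(model, subset_windows(batch, idx),
                              training = FALSE)$scores
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file with a sidecar `<path>.json` holding the
#' configuration for inspection without deserializing the weights.
#' @param model A `ppisite_model`.
#' @param path Checkpoint path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    lapply(model$config, function(x) if (length(x) == 1L) jsonlite::unbox(x) else x),
    paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "ppisite_model"))
  model
}

#' @export
print.ppisite_model <- function(x, ...) {
  cfg <- x$config
  ext <- conv_extents(cfg)
  cat("ppisite_model: window", cfg$window, "branches",
      paste(cfg$branches, collapse = "+"), "\n",
      " conv extents", paste(ext, collapse = "/"),
      "filters", paste(cfg$filters, collapse = "/"),
      "-> concat width", concat_width(cfg), "\n",
      " dense", paste(cfg$dense, collapse = "/"),
      "| parameters:", n_params(x), "\n")
  invisible(x)
}
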