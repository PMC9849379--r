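#' Configuration of the complex-valued CNN
#'
#' Architecture and training recipe for the comodulogram classifier: three
#' complex convolutional layers (3x3 kernels, size-preserving padding, each
#' followed by complex batch normalization and split ReLU) and four complex
#' fully connected layers, the last of width 2 (classes), read out to real
#' logits.  Defaults follow the training recipe of the method: 800 epochs,
#' batch size 128, learning rate .0025 halved at every multiple of 250
#' epochs, dropout .2 on the first fully connected layer, L2 weight decay
#' with lambda = .004 on the convolutional weights only, plain stochastic
#' gradient descent, cross-entropy loss.  Channel counts and kernel sizes
#' are implementation choices (the recipe does not fix them) and are fully
#' configurable.
#'
#' @param conv_channels Integer vector: output channels of the three (or
#'   more) convolutional layers.
#' @param kernel Odd kernel size.
#' @param fc_widths Widths of the fully connected layers; the last entry is
#'   the number of classes.
#' @param epochs,batch_size,lr Training length, batch size, initial
#'   learning rate.
#' @param lr_decay,lr_decay_every Learning-rate factor applied at every
#'   epoch that is a multiple of `lr_decay_every`.
#' @param dropout Dropout probability on the first fully connected layer
#'   (one mask zeroes real and imaginary parts together).
#' @param l2 Weight-decay coefficient on convolutional weights.
#' @param representation `"complex"` (CV-CNN on complex pixels),
#'   `"two_layer"` (real CNN on stacked real/imaginary channels) or
#'   `"strength"` (real CNN on the strength comodulogram only).
#' @param readout Logit mode, see [readout()]; defaults to `"modulus"` for
#'   the complex representation and `"real"` otherwise.
#' @param bn_mode Batch-normalization mode, see [complex_batchnorm()].
#' @param class_weights Optional numeric length-2 (normal, pathological)
#'   loss weights; `NULL` = unweighted.
#' @param seed Integer seed controlling initialization, batch order and
#'   dropout.
#' @return An object of class `cvcnn_config`.
#' @export
cvcnn_config <- function(conv_channels = c(16, 32, 64), kernel = 3,
                         fc_widths = c(128, 64, 32, 2), epochs = 800,
                         batch_size = 128, lr = 0.0025, lr_decay = 0.5,
                         lr_decay_every = 250, dropout = 0.2, l2 = 0.004,
                         representation = c("complex", "two_layer", "strength"),
                         readout = NULL, bn_mode = c("per_part", "whiten"),
                         class_weights = NULL, seed = 1L) {
  representation <- match.arg(representation)
  bn_mode <- match.arg(bn_mode)
  stopifnot(kernel %% 2 == 1, length(fc_widths) >= 1,
            epochs >= 1, batch_size >= 2, lr > 0, lr_decay > 0,
            lr_decay_every >= 1, dropout >= 0, dropout < 1, l2 >= 0)
  readout <- readout %||% if (representation == "complex") "modulus" else "real"
  structure(list(conv_channels = conv_channels, kernel = kernel,
                 fc_widths = fc_widths, epochs = epochs,
                 batch_size = batch_size, lr = lr, lr_decay = lr_decay,
                 lr_decay_every = lr_decay_every, dropout = dropout,
                 l2 = l2, representation = representation,
                 field = if (representation == "complex") "complex" else "real",
                 readout = readout, bn_mode = bn_mode,
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "cvcnn_config")
}

#' A small configuration for desk-scale experiments
#'
#' Same layer pattern as [cvcnn_config()] with fewer channels and epochs,
#' sized for 10x10 images and datasets of a few hundred windows per class.
#'
#' @param ... Overrides passed to [cvcnn_config()].
#' @export
cvcnn_config_small <- function(...) {
  args <- list(conv_channels = c(8, 8, 16), fc_widths = c(48, 24, 2),
               epochs = 200, lr = 0.02, ...)
  do.call(cvcnn_config, args[!duplicated(names(args), fromLast = TRUE)])
}

#' @export
print.cvcnn_config <- function(x, ...) {
  cat("<cvcnn_config> ", x$field, "-valued; conv ",
      paste(x$conv_channels, collapse = "/"), " (", x$kernel, "x", x$kernel,
      "), fc ", paste(x$fc_widths, collapse = "/"),
      "; ", x$epochs, " epochs, batch ", x$batch_size, ", lr ", x$lr,
      " (x", x$lr_decay, " every ", x$lr_decay_every, "), dropout ",
      x$dropout, ", l2 ", x$l2, ", readout ", x$readout, "\n", sep = "")
  invisible(x)
}

# ---- input representations -------------------------------------------------

#' Real-valued image representations of CV-PAC images
#'
#' Converts complex comodulogram images into the real-valued inputs used by
#' the baseline classifiers: `"two_layer"` stacks the real and the
#' imaginary part as two channels; `"strength"` keeps only the modulus
#' (one channel), discarding the coupled phases.
#'
#' @param images List of `cvpac_image` objects (or a dataset tibble with an
#'   `image` column).
#' @param mode `"two_layer"` or `"strength"`.
#' @return A numeric array `(height, width, channels, n_images)`.
#' @export
to_two_layer_real <- function(images, mode = c("two_layer", "strength")) {
  mode <- match.arg(mode)
  images <- as_image_list(images)
  d <- dim(images[[1]]$pixels)
  n <- length(images)
  if (mode == "two_layer") {
    out <- array(0, c(d[1], d[2], 2, n))
    for (i in seq_len(n)) {
      out[, , 1, i] <- Re(images[[i]]$pixels)
      out[, , 2, i] <- Im(images[[i]]$pixels)
    }
  } else {
    out <- array(0, c(d[1], d[2], 1, n))
    for (i in seq_len(n)) out[, , 1, i] <- Mod(images[[i]]$pixels)
  }
  out
}

as_image_list <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("image" %in% names(x))
    return(x$image)
  }
  if (inherits(x, "cvpac_image")) return(list(x))
  x
}

images_to_input <- function(images, representation) {
  images <- as_image_list(images)
  d <- dim(images[[1]]$pixels)
  n <- length(images)
  if (representation == "complex") {
    re <- array(0, c(d[1], d[2], 1, n))
    im <- array(0, c(d[1], d[2], 1, n))
    for (i in seq_len(n)) {
      re[, , 1, i] <- Re(images[[i]]$pixels)
      im[, , 1, i] <- Im(images[[i]]$pixels)
    }
    list(re = re, im = im)
  } else {
    re <- to_two_layer_real(images,
                            if (representation == "two_layer") "two_layer"
                            else "strength")
    list(re = re, im = array(0, dim(re)))
  }
}

# ---- model init ------------------------------------------------------------

init_cvcnn <- function(cfg, input_shape) {
  H <- input_shape[1]; W <- input_shape[2]; C <- input_shape[3]
  complexf <- cfg$field == "complex"
  rnd <- function(dims, fan_in) {
    array(rnorm(prod(dims), 0, sqrt(1 / fan_in)), dims)
  }
  zeros <- function(dims) array(0, dims)
  layers <- list()
  cin <- C
  k <- cfg$kernel
  for (ch in cfg$conv_channels) {
    fan <- k * k * cin * (if (complexf) 2 else 1)
    layers[[length(layers) + 1L]] <- list(
      type = "conv",
      wre = rnd(c(k, k, cin, ch), fan),
      wim = if (complexf) rnd(c(k, k, cin, ch), fan) else zeros(c(k, k, cin, ch)),
      bre = numeric(ch), bim = numeric(ch),
      gre = rep(1, ch), gim = rep(1, ch),
      bnre = numeric(ch), bnim = numeric(ch))
    cin <- ch
  }
  feat <- H * W * cin
  fin <- feat
  for (j in seq_along(cfg$fc_widths)) {
    out <- cfg$fc_widths[j]
    fan <- fin * (if (complexf) 2 else 1)
    layers[[length(layers) + 1L]] <- list(
      type = "fc",
      wre = matrix(rnorm(out * fin, 0, sqrt(1 / fan)), out, fin),
      wim = if (complexf) matrix(rnorm(out * fin, 0, sqrt(1 / fan)), out, fin)
            else matrix(0, out, fin),
      bre = numeric(out), bim = numeric(out))
    fin <- out
  }
  ro <- NULL
  if (cfg$readout == "affine") {
    K <- utils::tail(cfg$fc_widths, 1)
    ro <- list(wro = matrix(rnorm(K * 2 * K, 0, sqrt(1 / (2 * K))), K, 2 * K),
               bro = numeric(K))
  }
  bn_states <- lapply(cfg$conv_channels, bn_state)
  structure(list(cfg = cfg, layers = layers, readout = ro,
                 bn_states = bn_states, input_shape = input_shape,
                 class_map = c("normal", "pathological")),
            class = "cvcnn_model")
}

# ---- forward / backward ----------------------------------------------------

# conv activations flow as (channels x H*W*batch) matrices (see
# src/im2col.cpp for the layout); BN and ReLU act on them directly.
net_forward <- function(model, mre, mim, training) {
  cfg <- model$cfg
  caches <- vector("list", length(model$layers))
  H <- model$input_shape[1]; W <- model$input_shape[2]
  N <- as.integer(ncol(mre) / (H * W))
  h <- mre; hi <- mim
  pad <- (cfg$kernel - 1L) / 2L
  li <- 0L
  n_conv <- length(cfg$conv_channels)
  for (l in seq_len(n_conv)) {
    li <- li + 1L
    p <- model$layers[[li]]
    cv <- conv_fwd(h, hi, H, W, p$wre, p$wim, p$bre, p$bim, pad)
    bn <- bn_fwd(cv$re, cv$im, p$gre, p$gim, p$bnre, p$bnim,
                 model$bn_states[[l]], training, cfg$bn_mode)
    model$bn_states[[l]] <- bn$state
    rl <- relu_fwd(bn$re, bn$im)
    h <- rl$re; hi <- rl$im
    H <- cv$ho; W <- cv$wo
    caches[[li]] <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache)
  }
  ch <- nrow(h)
  flat_dim <- c(ch, H * W * N)
  dim(h) <- c(ch * H * W, N)
  dim(hi) <- c(ch * H * W, N)
  n_fc <- length(cfg$fc_widths)
  for (j in seq_len(n_fc)) {
    li <- li + 1L
    p <- model$layers[[li]]
    lf <- linear_fwd(h, hi, p$wre, p$wim, p$bre, p$bim)
    cache <- list(lin = lf$cache)
    if (j < n_fc) {
      rl <- relu_fwd(lf$re, lf$im)
      cache$relu <- rl$cache
      h <- rl$re; hi <- rl$im
      if (j == 1L) {
        dp <- dropout_fwd(h, hi, cfg$dropout, training)
        cache$drop <- dp$cache
        h <- dp$re; hi <- dp$im
      }
    } else {
      h <- lf$re; hi <- lf$im
    }
    caches[[li]] <- cache
  }
  ro <- readout_fwd(h, hi, cfg$readout,
                    model$readout$wro, model$readout$bro)
  list(logits = ro$logits, caches = caches, ro_cache = ro$cache,
       flat_dim = flat_dim, model = model)
}

net_backward <- function(model, fw, dlogits) {
  cfg <- model$cfg
  grads <- vector("list", length(model$layers))
  rb <- readout_bwd(dlogits, fw$ro_cache)
  gro <- if (cfg$readout == "affine") list(dwro = rb$dwro, dbro = rb$dbro)
  dre <- rb$dxre; dim_ <- rb$dxim
  n_conv <- length(cfg$conv_channels)
  n_fc <- length(cfg$fc_widths)
  for (j in rev(seq_len(n_fc))) {
    li <- n_conv + j
    cache <- fw$caches[[li]]
    if (j < n_fc) {
      if (j == 1L) {
        dp <- dropout_bwd(dre, dim_, cache$drop)
        dre <- dp$dre; dim_ <- dp$dim
      }
      rl <- relu_bwd(dre, dim_, cache$relu)
      dre <- rl$dre; dim_ <- rl$dim
    }
    lb <- linear_bwd(dre, dim_, cache$lin)
    grads[[li]] <- list(dwre = lb$dwre, dwim = lb$dwim,
                        dbre = lb$dbre, dbim = lb$dbim)
    dre <- lb$dxre; dim_ <- lb$dxim
  }
  fd <- fw$flat_dim
  dim(dre) <- fd
  dim(dim_) <- fd
  for (l in rev(seq_len(n_conv))) {
    cache <- fw$caches[[l]]
    rl <- relu_bwd(dre, dim_, cache$relu)
    bb <- bn_bwd(rl$dre, rl$dim, cache$bn)
    cb <- conv_bwd(bb$dxre, bb$dxim, cache$conv)
    grads[[l]] <- list(dwre = cb$dwre, dwim = cb$dwim,
                       dbre = cb$dbre, dbim = cb$dbim,
                       dgre = bb$dgre, dgim = bb$dgim,
                       dbnre = bb$dbre, dbnim = bb$dbim)
    dre <- cb$dxre; dim_ <- cb$dxim
  }
  list(layers = grads, readout = gro)
}

sgd_step <- function(model, grads, lr) {
  cfg <- model$cfg
  complexf <- cfg$field == "complex"
  n_conv <- length(cfg$conv_channels)
  for (li in seq_along(model$layers)) {
    p <- model$layers[[li]]
    g <- grads$layers[[li]]
    if (li <= n_conv && cfg$l2 > 0) {      # weight decay on conv weights only
      g$dwre <- g$dwre + cfg$l2 * p$wre
      g$dwim <- g$dwim + cfg$l2 * p$wim
    }
    p$wre <- p$wre - lr * g$dwre
    p$bre <- p$bre - lr * g$dbre
    if (complexf) {
      p$wim <- p$wim - lr * g$dwim
      p$bim <- p$bim - lr * g$dbim
    }
    if (p$type == "conv") {
      p$gre <- p$gre - lr * g$dgre
      p$bnre <- p$bnre - lr * g$dbnre
      if (complexf) {
        p$gim <- p$gim - lr * g$dgim
        p$bnim <- p$bnim - lr * g$dbnim
      }
    }
    model$layers[[li]] <- p
  }
  if (!is.null(model$readout)) {
    model$readout$wro <- model$readout$wro - lr * grads$readout$dwro
    model$readout$bro <- model$readout$bro - lr * grads$readout$dbro
  }
  model
}

#' Effective learning rate at an epoch
#'
#' The stepwise schedule: the base rate multiplied by `lr_decay` once for
#' every completed multiple of `lr_decay_every` epochs (epoch 250 already
#' runs at half the base rate with the defaults).
#'
#' @param cfg A [cvcnn_config()].
#' @param epoch Epoch number (1-based).
#' @return The learning rate used in that epoch.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$lr * cfg$lr_decay^(epoch %/% cfg$lr_decay_every)
}

# ---- training --------------------------------------------------------------

#' Train the (complex-valued) convolutional network
#'
#' Trains the classifier of [cvcnn_config()] on a labeled image dataset by
#' mini-batch stochastic gradient descent with the stepped learning-rate
#' schedule, cross-entropy loss, dropout on the first fully connected
#' layer, and weight decay on the convolutional weights.  With
#' `representation = "complex"` all weights and feature maps are complex;
#' the `"two_layer"` and `"strength"` representations train the same
#' architecture restricted to real arithmetic (the traditional-CNN
#' baselines).  Training is deterministic given `config$seed`.
#'
#' @param data A dataset tibble with `image` (list of `cvpac_image`) and
#'   `label` (`"normal"` / `"pathological"`) columns, or a list with
#'   elements `images` and `labels`.
#' @param config A [cvcnn_config()].
#' @param verbose Print the loss every `verbose` epochs (0 = silent).
#' @return An object of class `cvcnn_model` with the learned weights,
#'   `training_log` (tibble: epoch, lr, loss) and the configuration.
#' @export
cvcnn_train <- function(data, config = cvcnn_config(), verbose = 0) {
  if (is.data.frame(data)) {
    stopifnot(all(c("image", "label") %in% names(data)))
    images <- data$image
    labels <- data$label
  } else {
    images <- data$images
    labels <- data$labels
  }
  labels <- as.character(labels)
  classes <- c("normal", "pathological")
  if (!all(labels %in% classes)) {
    stop("labels must be 'normal' or 'pathological'", call. = FALSE)
  }
  y <- match(labels, classes)
  if (length(unique(y)) < 2) {
    stop("training data contains a single class", call. = FALSE)
  }
  inp <- images_to_input(images, config$representation)
  N <- dim(inp$re)[4]
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  model <- init_cvcnn(config, dim(inp$re)[1:3])
  HW <- prod(model$input_shape[1:2])
  Mre <- to_mat(inp$re)
  Mim <- to_mat(inp$im)
  log <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, epoch)
    perm <- sample.int(N)
    losses <- c()
    for (b0 in seq(1, N, by = config$batch_size)) {
      idx <- perm[b0:min(b0 + config$batch_size - 1L, N)]
      if (length(idx) < 2) next                    # BN needs >= 2
      cols <- rep((idx - 1L) * HW, each = HW) + seq_len(HW)
      bre <- Mre[, cols, drop = FALSE]
      bim <- Mim[, cols, drop = FALSE]
      fw <- net_forward(model, bre, bim, training = TRUE)
      model <- fw$model                            # BN running stats
      sx <- softmax_xent(fw$logits, y[idx], config$class_weights)
      if (!is.finite(sx$loss)) {
        stop("non-finite loss at epoch ", epoch, call. = FALSE)
      }
      grads <- net_backward(model, fw, sx$dlogits)
      model <- sgd_step(model, grads, lr)
      losses <- c(losses, sx$loss)
    }
    log[[epoch]] <- tibble(epoch = epoch, lr = lr, loss = mean(losses))
    if (verbose > 0 && epoch %% verbose == 0) {
      message(sprintf("epoch %4d  lr %.5f  loss %.4f", epoch, lr,
                      mean(losses)))
    }
  }
  model$training_log <- dplyr::bind_rows(log)
  model$class_map <- classes
  model
}

#' @export
print.cvcnn_model <- function(x, ...) {
  cat("<cvcnn_model> ", x$cfg$field, "-valued, input ",
      paste(x$input_shape, collapse = "x"), sep = "")
  if (!is.null(x$training_log)) {
    cat("; trained ", max(x$training_log$epoch), " epochs, final loss ",
        signif(utils::tail(x$training_log$loss, 1), 4), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Predict pathological probabilities for CV-PAC images
#'
#' Runs the trained network in evaluation mode (batch-normalization
#' running statistics frozen, no dropout) and returns the softmax
#' probability of the pathological class per image.
#'
#' @param object A trained [cvcnn_train()] model.
#' @param newdata A dataset tibble with an `image` column, or a list of
#'   `cvpac_image`s.
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return If `newdata` is a tibble, the tibble with an added
#'   `prob_pathological` column; otherwise a numeric vector.
#' @export
predict.cvcnn_model <- function(object, newdata, batch_size = 256, ...) {
  images <- as_image_list(newdata)
  inp <- images_to_input(images, object$cfg$representation)
  if (!all(dim(inp$re)[1:3] == object$input_shape)) {
    stop("image shape does not match the trained model", call. = FALSE)
  }
  N <- dim(inp$re)[4]
  HW <- prod(object$input_shape[1:2])
  Mre <- to_mat(inp$re)
  Mim <- to_mat(inp$im)
  probs <- numeric(N)
  for (b0 in seq(1, N, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, N)
    cols <- rep((idx - 1L) * HW, each = HW) + seq_len(HW)
    fw <- net_forward(object, Mre[, cols, drop = FALSE],
                      Mim[, cols, drop = FALSE], training = FALSE)
    K <- nrow(fw$logits)
    m <- apply(fw$logits, 2, max)
    e <- exp(sweep(fw$logits, 2, m))
    p <- sweep(e, 2, colSums(e), "/")
    probs[idx] <- p[match("pathological", object$class_map), ]
  }
  if (is.data.frame(newdata)) {
    newdata$prob_pathological <- probs
    newdata
  } else probs
}

# flatten / restore all trainable parameters (used by the gradient checks)
cvcnn_flatten <- function(model) {
  out <- list()
  for (li in seq_along(model$layers)) {
    p <- model$layers[[li]]
    keep <- intersect(names(p), c("wre", "wim", "bre", "bim",
                                  "gre", "gim", "bnre", "bnim"))
    for (nm in keep) out[[paste0("L", li, ".", nm)]] <- p[[nm]]
  }
  if (!is.null(model$readout)) {
    out[["RO.wro"]] <- model$readout$wro
    out[["RO.bro"]] <- model$readout$bro
  }
  out
}

cvcnn_restore <- function(model, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (parts[1] == "RO") {
      model$readout[[parts[2]]] <- params[[nm]]
    } else {
      li <- as.integer(sub("L", "", parts[1]))
      model$layers[[li]][[parts[2]]] <- params[[nm]]
    }
  }
  model
}
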