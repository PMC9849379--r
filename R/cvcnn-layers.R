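#' Complex tensor
#'
#' A pair of equal-shaped real arrays holding the real and imaginary parts
#' of feature maps or weights.  `im = NULL` denotes an exactly-zero
#' imaginary part (used by the real-valued baseline network).
#'
#' @param re,im Numeric arrays of identical shape (`im` optional).
#' @return An object of class `complex_tensor`.
#' @export
complex_tensor <- function(re, im = NULL) {
  if (!is.null(im) && !identical(dim(re) %||% length(re),
                                 dim(im) %||% length(im))) {
    stop("real and imaginary parts must have the same shape", call. = FALSE)
  }
  structure(list(re = re, im = im %||% array(0, dim(re) %||% length(re))),
            class = "complex_tensor")
}

#' @export
print.complex_tensor <- function(x, ...) {
  cat("<complex_tensor> shape ",
      paste(dim(x$re) %||% length(x$re), collapse = " x "), "\n", sep = "")
  invisible(x)
}

# ---- complex 2-D convolution ----------------------------------------------

# Feature maps flow through the convolutional stack as (C x H*W*N)
# matrices (channel fastest down the rows; columns ordered spatial row,
# spatial column, batch).  im2col/col2im (src/im2col.cpp) build and
# scatter the patch matrix in that layout.

# weight array (k, k, C_in, C_out) -> matrix (C_out, k*k*C_in) matching
# the im2col row order (channel fastest, kernel row, kernel column)
wmat <- function(w) {
  d <- dim(w)
  t(matrix(aperm(w, c(3, 1, 2, 4)), ncol = d[4]))
}

wmat_inv <- function(Wm, k, C_in, C_out) {
  aperm(array(t(Wm), c(C_in, k, k, C_out)), c(2, 3, 1, 4))
}

# 4-D (H, W, C, N) array <-> matrix layout
to_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(3, 1, 2, 4)), nrow = d[3])
}

to_arr <- function(m, H, W, N) {
  C <- nrow(m)
  aperm(array(m, c(C, H, W, N)), c(2, 3, 1, 4))
}

conv_fwd <- function(mre, mim, H, W, wre, wim, bre, bim, pad = 0L) {
  d <- dim(wre)
  k <- d[1]; C_in <- d[3]; C_out <- d[4]
  N <- as.integer(ncol(mre) / (H * W))
  Xre <- im2col_cpp(mre, H, W, N, k, pad)
  Xim <- im2col_cpp(mim, H, W, N, k, pad)
  Wre <- wmat(wre); Wim <- wmat(wim)
  Yre <- Wre %*% Xre - Wim %*% Xim + as.vector(bre)
  Yim <- Wre %*% Xim + Wim %*% Xre + as.vector(bim)
  ho <- H + 2 * pad - k + 1L
  wo <- W + 2 * pad - k + 1L
  list(re = Yre, im = Yim, ho = ho, wo = wo,
       cache = list(Xre = Xre, Xim = Xim, Wre = Wre, Wim = Wim,
                    k = k, pad = pad, C_in = C_in, C_out = C_out,
                    H = H, W = W, N = N))
}

conv_bwd <- function(dYre, dYim, cache) {
  Xre <- cache$Xre; Xim <- cache$Xim
  dWre <- tcrossprod(dYre, Xre) + tcrossprod(dYim, Xim)
  dWim <- tcrossprod(dYim, Xre) - tcrossprod(dYre, Xim)
  dXre <- crossprod(cache$Wre, dYre) + crossprod(cache$Wim, dYim)
  dXim <- crossprod(cache$Wre, dYim) - crossprod(cache$Wim, dYre)
  list(dwre = wmat_inv(dWre, cache$k, cache$C_in, cache$C_out),
       dwim = wmat_inv(dWim, cache$k, cache$C_in, cache$C_out),
       dbre = rowSums(dYre), dbim = rowSums(dYim),
       dxre = col2im_cpp(dXre, cache$H, cache$W, cache$N, cache$k, cache$pad),
       dxim = col2im_cpp(dXim, cache$H, cache$W, cache$N, cache$k, cache$pad))
}

#' Complex-valued 2-D convolution
#'
#' Cross-correlates a complex input with complex kernels using the complex
#' product rule: for weights `A + iB` and input `R + iI` the output is
#' `(A*R - B*I) + i(A*I + B*R)`, where `*` is real 2-D cross-correlation;
#' a complex bias is added per output channel.
#'
#' @param x A [complex_tensor()] with parts of shape
#'   `(height, width, in_channels, batch)`.
#' @param w A `complex_tensor` of kernels, shape
#'   `(k, k, in_channels, out_channels)`.
#' @param b Optional `complex_tensor` bias of length `out_channels`.
#' @param pad Zero-padding per side (0 = valid convolution).
#' @return A `complex_tensor` of shape
#'   `(height - k + 1 + 2 pad, ..., out_channels, batch)`.
#' @export
complex_conv2d <- function(x, w, b = NULL, pad = 0L) {
  stopifnot(inherits(x, "complex_tensor"), inherits(w, "complex_tensor"))
  if (dim(x$re)[3] != dim(w$re)[3]) {
    stop("input channels (", dim(x$re)[3], ") do not match kernel channels (",
         dim(w$re)[3], ")", call. = FALSE)
  }
  if (dim(w$re)[1] > dim(x$re)[1] + 2 * pad) {
    stop("kernel larger than (padded) input", call. = FALSE)
  }
  d <- dim(x$re)
  out <- conv_fwd(to_mat(x$re), to_mat(x$im), d[1], d[2], w$re, w$im,
                  if (is.null(b)) 0 else as.vector(b$re),
                  if (is.null(b)) 0 else as.vector(b$im), pad)
  complex_tensor(to_arr(out$re, out$ho, out$wo, d[4]),
                 to_arr(out$im, out$ho, out$wo, d[4]))
}

# ---- complex linear --------------------------------------------------------

linear_fwd <- function(xre, xim, wre, wim, bre, bim) {
  Yre <- wre %*% xre - wim %*% xim + as.vector(bre)
  Yim <- wre %*% xim + wim %*% xre + as.vector(bim)
  list(re = Yre, im = Yim, cache = list(xre = xre, xim = xim,
                                        wre = wre, wim = wim))
}

linear_bwd <- function(dre, dim_, cache) {
  list(dwre = tcrossprod(dre, cache$xre) + tcrossprod(dim_, cache$xim),
       dwim = tcrossprod(dim_, cache$xre) - tcrossprod(dre, cache$xim),
       dbre = rowSums(dre), dbim = rowSums(dim_),
       dxre = crossprod(cache$wre, dre) + crossprod(cache$wim, dim_),
       dxim = crossprod(cache$wre, dim_) - crossprod(cache$wim, dre))
}

#' Complex-valued fully connected layer
#'
#' Complex matrix product `y = W x + b` on a features-by-batch input.
#'
#' @param x A [complex_tensor()], parts of shape `(features, batch)`.
#' @param w A `complex_tensor` of shape `(out_features, features)`.
#' @param b Optional `complex_tensor` of length `out_features`.
#' @return A `complex_tensor` of shape `(out_features, batch)`.
#' @export
complex_linear <- function(x, w, b = NULL) {
  stopifnot(inherits(x, "complex_tensor"), inherits(w, "complex_tensor"))
  xre <- as.matrix(x$re); xim <- as.matrix(x$im)
  if (ncol(w$re) != nrow(xre)) stop("width mismatch", call. = FALSE)
  bre <- if (is.null(b)) 0 else as.vector(b$re)
  bim <- if (is.null(b)) 0 else as.vector(b$im)
  out <- linear_fwd(xre, xim, as.matrix(w$re), as.matrix(w$im), bre, bim)
  complex_tensor(out$re, out$im)
}

# ---- split ReLU ------------------------------------------------------------

#' Split rectified linear activation
#'
#' Applies ReLU to the real and the imaginary part separately:
#' `max(Re z, 0) + i max(Im z, 0)`.
#'
#' @param x A [complex_tensor()].
#' @return A `complex_tensor` of the same shape.
#' @export
split_relu <- function(x) {
  stopifnot(inherits(x, "complex_tensor"))
  complex_tensor(pmax(x$re, 0), pmax(x$im, 0))
}

relu_fwd <- function(re, im) {
  mre <- re > 0; mim <- im > 0
  list(re = re * mre, im = im * mim, cache = list(mre = mre, mim = mim))
}

relu_bwd <- function(dre, dim_, cache) {
  list(dre = dre * cache$mre, dim = dim_ * cache$mim)
}

# ---- complex batch normalization ------------------------------------------

# Per-part mode: real and imaginary parts standardized independently per
# channel with learned per-part affine.  Whiten mode: the 2x2
# real/imaginary covariance per channel is removed by a Cholesky-based
# decorrelation before the affine.  x parts are (channels x batch-positions)
# matrices; statistics are taken over columns.

bn_fwd <- function(xre, xim, gre, gim, bre, bim, state, training,
                   mode = "per_part", eps = 1e-5, momentum = 0.1) {
  gre <- as.vector(gre); gim <- as.vector(gim)
  bre <- as.vector(bre); bim <- as.vector(bim)
  if (training && ncol(xre) < 2) stop("batch normalization needs batch size >= 2",
                                      call. = FALSE)
  if (training) {
    mre <- rowMeans(xre); mim <- rowMeans(xim)
    ure <- xre - mre; uim <- xim - mim
    vre <- rowMeans(ure^2); vim <- rowMeans(uim^2)
    vri <- rowMeans(ure * uim)
    state$mean_re <- (1 - momentum) * state$mean_re + momentum * mre
    state$mean_im <- (1 - momentum) * state$mean_im + momentum * mim
    state$var_re <- (1 - momentum) * state$var_re + momentum * vre
    state$var_im <- (1 - momentum) * state$var_im + momentum * vim
    state$cov_ri <- (1 - momentum) * state$cov_ri + momentum * vri
  } else {
    mre <- state$mean_re; mim <- state$mean_im
    vre <- state$var_re; vim <- state$var_im
    vri <- state$cov_ri
    ure <- xre - mre; uim <- xim - mim
  }
  if (mode == "per_part") {
    sre <- sqrt(vre + eps); sim <- sqrt(vim + eps)
    yre <- ure / sre; yim <- uim / sim
    cache <- list(mode = mode, ure = ure, uim = uim, sre = sre, sim = sim,
                  yre = yre, yim = yim, gre = gre, gim = gim,
                  training = training)
  } else {
    # Cholesky whitening: C = [[a, b], [b, c]], y1 = u1 / sqrt(a),
    # y2 = (u2 - (b/a) u1) / sqrt(c - b^2/a)
    a <- vre + eps; b <- vri; cc <- vim + eps
    sa <- sqrt(a)
    r <- b / a
    s2 <- sqrt(cc - b^2 / a + eps)
    yre <- ure / sa
    yim <- (uim - r * ure) / s2
    cache <- list(mode = mode, ure = ure, uim = uim, a = a, b = b, cc = cc,
                  sa = sa, r = r, s2 = s2, yre = yre, yim = yim,
                  gre = gre, gim = gim, training = training)
  }
  list(re = gre * yre + bre, im = gim * yim + bim, state = state,
       cache = cache)
}

bn_bwd <- function(dre, dim_, cache) {
  n <- ncol(dre)
  dgre <- rowSums(dre * cache$yre)
  dgim <- rowSums(dim_ * cache$yim)
  dbre <- rowSums(dre)
  dbim <- rowSums(dim_)
  dyre <- dre * cache$gre
  dyim <- dim_ * cache$gim
  if (!cache$training) {
    # statistics frozen: plain linear map
    if (cache$mode == "per_part") {
      return(list(dgre = dgre, dgim = dgim, dbre = dbre, dbim = dbim,
                  dxre = dyre / cache$sre, dxim = dyim / cache$sim))
    }
    dxim <- dyim / cache$s2
    dxre <- dyre / cache$sa - cache$r * dxim
    return(list(dgre = dgre, dgim = dgim, dbre = dbre, dbim = dbim,
                dxre = dxre, dxim = dxim))
  }
  if (cache$mode == "per_part") {
    dxre <- bn_part_bwd(dyre, cache$ure, cache$sre, n)
    dxim <- bn_part_bwd(dyim, cache$uim, cache$sim, n)
    return(list(dgre = dgre, dgim = dgim, dbre = dbre, dbim = dbim,
                dxre = dxre, dxim = dxim))
  }
  # whiten mode: backprop through u -> (a, b, c) -> (y1, y2)
  u1 <- cache$ure; u2 <- cache$uim
  a <- cache$a; b <- cache$b; sa <- cache$sa; r <- cache$r; s2 <- cache$s2
  d1 <- dyre; d2 <- dyim
  # y2 = w / s2, w = u2 - r u1
  w <- u2 - r * u1
  dw <- d2 / s2
  ds2 <- -rowSums(d2 * w) / s2^2
  du2 <- dw
  du1 <- -r * dw
  dr <- -rowSums(dw * u1)
  # y1 = u1 / sa
  du1 <- du1 + d1 / sa
  dsa <- -rowSums(d1 * u1) / sa^2
  # s2 = sqrt(cc - b^2/a + eps); r = b/a; sa = sqrt(a)
  dcc <- ds2 / (2 * s2)
  db <- -ds2 * b / (a * s2) + dr / a
  da <- ds2 * b^2 / (2 * a^2 * s2) - dr * b / a^2 + dsa / (2 * sa)
  # a = mean(u1^2)+eps, b = mean(u1 u2), cc = mean(u2^2)+eps over columns
  du1 <- du1 + (2 * da * u1 + db * u2) / n
  du2 <- du2 + (2 * dcc * u2 + db * u1) / n
  # u = x - rowMeans(x)
  dxre <- du1 - rowMeans(du1)
  dxim <- du2 - rowMeans(du2)
  list(dgre = dgre, dgim = dgim, dbre = dbre, dbim = dbim,
       dxre = dxre, dxim = dxim)
}

bn_part_bwd <- function(dy, u, s, n) {
  (dy - rowMeans(dy) - u * rowMeans(dy * u) / s^2) / s
}

#' Complex batch normalization
#'
#' Normalizes complex feature maps per channel over a batch.  In the
#' default `"per_part"` mode the real and imaginary parts are standardized
#' independently (each to mean 0, variance 1 in training mode) and given a
#' learned per-part affine.  In `"whiten"` mode the per-channel 2x2
#' covariance between the parts is additionally removed by a Cholesky
#' decorrelation before the affine.  Running statistics (exponential
#' moving averages) are updated in training mode and used verbatim in eval
#' mode.
#'
#' @param x A [complex_tensor()], parts of shape `(channels, batch)` (or
#'   any array whose first dimension is channels; it is flattened to
#'   channels x rest).
#' @param gamma,beta `complex_tensor`s of per-channel affine parameters
#'   (defaults: gamma = 1 + 1i, beta = 0).
#' @param state Running statistics as returned by a previous call, or
#'   `NULL` to initialize.
#' @param training Logical: batch statistics (TRUE) or running statistics.
#' @param mode `"per_part"` or `"whiten"`.
#' @param eps Variance floor.
#' @param momentum Running-statistics update weight.
#' @return List with `out` (a `complex_tensor`) and the updated `state`.
#' @export
complex_batchnorm <- function(x, gamma = NULL, beta = NULL, state = NULL,
                              training = TRUE, mode = c("per_part", "whiten"),
                              eps = 1e-5, momentum = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "complex_tensor"))
  d <- dim(x$re) %||% c(length(x$re), 1L)
  ch <- d[1]
  xre <- matrix(x$re, nrow = ch)
  xim <- matrix(x$im, nrow = ch)
  state <- state %||% bn_state(ch)
  gre <- if (is.null(gamma)) rep(1, ch) else as.vector(gamma$re)
  gim <- if (is.null(gamma)) rep(1, ch) else as.vector(gamma$im)
  bre <- if (is.null(beta)) rep(0, ch) else as.vector(beta$re)
  bim <- if (is.null(beta)) rep(0, ch) else as.vector(beta$im)
  out <- bn_fwd(xre, xim, gre, gim, bre, bim, state, training, mode, eps,
                momentum)
  list(out = complex_tensor(array(out$re, d), array(out$im, d)),
       state = out$state)
}

bn_state <- function(ch) {
  list(mean_re = rep(0, ch), mean_im = rep(0, ch),
       var_re = rep(1, ch), var_im = rep(1, ch), cov_ri = rep(0, ch))
}

# ---- readout ---------------------------------------------------------------

readout_fwd <- function(xre, xim, mode, wro = NULL, bro = NULL, eps = 1e-9) {
  switch(mode,
    modulus = {
      m <- sqrt(xre^2 + xim^2 + eps^2)
      list(logits = m, cache = list(mode = mode, xre = xre, xim = xim, m = m))
    },
    real = list(logits = xre, cache = list(mode = mode)),
    affine = {
      z <- rbind(xre, xim)
      list(logits = wro %*% z + as.vector(bro),
           cache = list(mode = mode, z = z, wro = wro, k = nrow(xre)))
    })
}

readout_bwd <- function(dlog, cache) {
  switch(cache$mode,
    modulus = list(dxre = dlog * cache$xre / cache$m,
                   dxim = dlog * cache$xim / cache$m),
    real = list(dxre = dlog, dxim = array(0, dim(dlog))),
    affine = {
      dz <- t(cache$wro) %*% dlog
      k <- cache$k
      list(dxre = dz[seq_len(k), , drop = FALSE],
           dxim = dz[k + seq_len(k), , drop = FALSE],
           dwro = dlog %*% t(cache$z), dbro = rowSums(dlog))
    })
}

#' Readout of complex class activations to real logits
#'
#' Converts the final complex activations (one per class) to real class
#' scores.  `"modulus"` (default) takes the complex modulus, making the
#' scores invariant to a global phase rotation of the final layer;
#' `"real"` takes the real part; `"affine"` maps the concatenated real and
#' imaginary parts through one real affine layer (`w`, `b`).
#'
#' @param x A [complex_tensor()] of shape `(classes, batch)`.
#' @param mode `"modulus"`, `"real"` or `"affine"`.
#' @param w,b Real weight matrix `(classes, 2 classes)` and bias for
#'   `"affine"` mode.
#' @return A real matrix of class scores `(classes, batch)`.
#' @export
readout <- function(x, mode = c("modulus", "real", "affine"), w = NULL,
                    b = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "complex_tensor"))
  xre <- as.matrix(x$re); xim <- as.matrix(x$im)
  if (mode == "affine" && is.null(w)) {
    stop("affine readout needs a weight matrix", call. = FALSE)
  }
  readout_fwd(xre, xim, mode, w, if (is.null(b)) 0 else as.vector(b))$logits
}

# ---- dropout ---------------------------------------------------------------

# One mask zeroes real and imaginary parts together (inverted scaling).
dropout_fwd <- function(xre, xim, p, training) {
  if (!training || p <= 0) {
    return(list(re = xre, im = xim, cache = list(mask = NULL)))
  }
  mask <- (matrix(runif(length(xre)), nrow(xre)) >= p) / (1 - p)
  list(re = xre * mask, im = xim * mask, cache = list(mask = mask))
}

dropout_bwd <- function(dre, dim_, cache) {
  if (is.null(cache$mask)) return(list(dre = dre, dim = dim_))
  list(dre = dre * cache$mask, dim = dim_ * cache$mask)
}

# ---- softmax cross-entropy -------------------------------------------------

softmax_xent <- function(logits, y, class_w = NULL) {
  # logits (K x N), y integer class index 1..K
  K <- nrow(logits); N <- ncol(logits)
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  p <- sweep(e, 2, colSums(e), "/")
  w <- if (is.null(class_w)) rep(1, N) else class_w[y]
  idx <- cbind(y, seq_len(N))
  py <- p[cbind(y, seq_len(N))]
  loss <- -sum(w * log(pmax(py, 1e-300))) / sum(w)
  dlog <- sweep(p, 2, w, "*")
  dlog[idx] <- dlog[idx] - w
  dlog <- dlog / sum(w)
  list(loss = loss, probs = p, dlogits = dlog)
}
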