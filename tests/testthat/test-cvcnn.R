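test_that("complex convolution matches the per-pixel oracle", {
  # 1x1 kernel w = 1+i on constant input 1-i -> constant 2
  x <- complex_tensor(array(1, c(3, 3, 1, 1)), array(-1, c(3, 3, 1, 1)))
  w <- complex_tensor(array(1, c(1, 1, 1, 1)), array(1, c(1, 1, 1, 1)))
  y <- complex_conv2d(x, w)
  expect_equal(as.vector(y$re), rep(2, 9))
  expect_equal(as.vector(y$im), rep(0, 9))
  # purely real weights and input -> purely real output
  set.seed(4)
  xr <- complex_tensor(array(rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2)))
  wr <- complex_tensor(array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4)))
  expect_equal(max(abs(complex_conv2d(xr, wr)$im)), 0)
  # random complex case vs. the loop oracle
  xc <- array(complex(real = rnorm(5 * 5 * 2 * 2),
                      imaginary = rnorm(5 * 5 * 2 * 2)), c(5, 5, 2, 2))
  wc <- array(complex(real = rnorm(3 * 3 * 2 * 3),
                      imaginary = rnorm(3 * 3 * 2 * 3)), c(3, 3, 2, 3))
  y2 <- complex_conv2d(complex_tensor(Re(xc), Im(xc)),
                       complex_tensor(Re(wc), Im(wc)))
  ora <- conv_oracle(xc, wc)
  expect_equal(y2$re, Re(ora), tolerance = 1e-6)
  expect_equal(y2$im, Im(ora), tolerance = 1e-6)
  expect_error(complex_conv2d(xr, complex_tensor(array(0, c(3, 3, 5, 1)))),
               "channels")
})

test_that("complex linear layer matches explicit complex expansion", {
  x <- complex_tensor(matrix(1), matrix(0))
  wi <- complex_tensor(matrix(0), matrix(1))          # w = i
  y <- complex_linear(x, wi)
  expect_equal(as.vector(y$re), 0)
  expect_equal(as.vector(y$im), 1)                    # i * 1 = i
  # identity weight, zero bias
  xr <- complex_tensor(matrix(rnorm(8), 4), matrix(rnorm(8), 4))
  id <- complex_tensor(diag(4), matrix(0, 4, 4))
  yid <- complex_linear(xr, id)
  expect_equal(yid$re, xr$re)
  expect_equal(yid$im, xr$im)
  # random case vs (a+bi)(c+di) oracle
  set.seed(8)
  W <- matrix(complex(real = rnorm(12), imaginary = rnorm(12)), 3, 4)
  X <- matrix(complex(real = rnorm(8), imaginary = rnorm(8)), 4, 2)
  b <- complex(real = rnorm(3), imaginary = rnorm(3))
  Y <- W %*% X + b
  got <- complex_linear(complex_tensor(Re(X), Im(X)),
                        complex_tensor(Re(W), Im(W)),
                        complex_tensor(Re(b), Im(b)))
  expect_equal(got$re, Re(Y), tolerance = 1e-6)
  expect_equal(got$im, Im(Y), tolerance = 1e-6)
  expect_error(complex_linear(xr, complex_tensor(matrix(0, 2, 5))), "width")
})

test_that("split ReLU rectifies the parts independently", {
  x <- complex_tensor(matrix(c(-1, 3, 0, 2)), matrix(c(2, -4, 0, 5)))
  y <- split_relu(x)
  expect_equal(as.vector(y$re), c(0, 3, 0, 2))
  expect_equal(as.vector(y$im), c(2, 0, 0, 5))
  xp <- complex_tensor(matrix(runif(10)), matrix(runif(10)))
  yp <- split_relu(xp)
  expect_equal(yp$re, xp$re)
  expect_equal(yp$im, xp$im)
})

test_that("complex batch normalization standardizes per part in train mode", {
  set.seed(10)
  x <- complex_tensor(matrix(rnorm(5 * 200, 3, 2), 5),
                      matrix(rnorm(5 * 200, -1, 0.5), 5))
  out <- complex_batchnorm(x, training = TRUE)
  expect_equal(rowMeans(out$out$re), rep(0, 5), tolerance = 1e-5)
  # batch (population) variance -> 1
  expect_equal(rowMeans(out$out$re^2), rep(1, 5), tolerance = 1e-3)
  expect_equal(rowMeans(out$out$im), rep(0, 5), tolerance = 1e-5)
  # constant batch -> zero-centered output (the learned shift, here 0)
  xc <- complex_tensor(matrix(7, 3, 10), matrix(-2, 3, 10))
  oc <- complex_batchnorm(xc, training = TRUE)
  expect_equal(max(abs(oc$out$re)), 0, tolerance = 1e-6)
  # already-standardized input with identity affine passes through
  std <- function(m) {
    u <- m - rowMeans(m)
    u / sqrt(rowMeans(u^2))
  }
  xs <- complex_tensor(std(x$re), std(x$im))
  os <- complex_batchnorm(xs, training = TRUE)
  expect_equal(os$out$re, xs$re, tolerance = 1e-2)
  # whiten mode removes the real-imaginary correlation
  re <- matrix(rnorm(2 * 500), 2)
  xw <- complex_tensor(re, 0.9 * re + 0.1 * matrix(rnorm(2 * 500), 2))
  ow <- complex_batchnorm(xw, training = TRUE, mode = "whiten")
  expect_lt(max(abs(cor(ow$out$re[1, ], ow$out$im[1, ]))), 0.05)
  expect_error(complex_batchnorm(
    complex_tensor(matrix(1, 2, 1), matrix(0, 2, 1)), training = TRUE),
    "batch size")
})

test_that("batch-norm running statistics drive eval mode", {
  set.seed(12)
  st <- NULL
  for (i in 1:60) {
    x <- complex_tensor(matrix(rnorm(3 * 50, 2, 3), 3),
                        matrix(rnorm(3 * 50), 3))
    st <- complex_batchnorm(x, state = st, training = TRUE)$state
  }
  expect_equal(st$mean_re, rep(2, 3), tolerance = 0.5)
  expect_equal(st$var_re, rep(9, 3), tolerance = 2)
  xe <- complex_tensor(matrix(2, 3, 4), matrix(0, 3, 4))
  oe <- complex_batchnorm(xe, state = st, training = FALSE)
  expect_lt(max(abs(oe$out$re)), 0.3)   # near the running mean -> near 0
  # eval mode twice is identical (stats frozen)
  oe2 <- complex_batchnorm(xe, state = st, training = FALSE)
  expect_identical(oe$out$re, oe2$out$re)
})

test_that("readout modes map complex activations to logits", {
  x <- complex_tensor(matrix(c(3, 0)), matrix(c(4, 0)))
  expect_equal(as.vector(readout(x, "modulus")), c(5, 0), tolerance = 1e-6)
  xr <- complex_tensor(matrix(c(1.5, -2)), matrix(c(0, 0)))
  expect_equal(as.vector(readout(xr, "real")), c(1.5, -2))
  # modulus readout is invariant to a global phase rotation
  set.seed(13)
  z <- matrix(complex(real = rnorm(6), imaginary = rnorm(6)), 2, 3)
  r1 <- readout(complex_tensor(Re(z), Im(z)), "modulus")
  zr <- z * exp(1i * 1.1)
  r2 <- readout(complex_tensor(Re(zr), Im(zr)), "modulus")
  expect_equal(r1, r2, tolerance = 1e-9)
  # affine mode needs weights and applies them
  W <- matrix(rnorm(2 * 4), 2, 4)
  ra <- readout(complex_tensor(Re(z), Im(z)), "affine", w = W)
  expect_equal(ra, W %*% rbind(Re(z), Im(z)), tolerance = 1e-9)
  expect_error(readout(complex_tensor(Re(z), Im(z)), "affine"), "weight")
})

test_that("learning rate follows the stepped decay schedule", {
  cfg <- cvcnn_config()
  expect_equal(lr_at_epoch(cfg, 1), 0.0025)
  expect_equal(lr_at_epoch(cfg, 249), 0.0025)
  expect_equal(lr_at_epoch(cfg, 250), 0.00125)
  expect_equal(lr_at_epoch(cfg, 500), 0.000625)
  expect_equal(lr_at_epoch(cfg, 750), 0.0003125)
  expect_equal(lr_at_epoch(cfg, 800), 0.0003125)
})

test_that("weight decay applies to convolutional weights only", {
  d <- tiny_dataset(n_per_class = 6, windows_per_channel = 3,
                    patients = "A", seed = 3)
  cfg0 <- cvcnn_config(conv_channels = 4, fc_widths = c(8, 2), epochs = 1,
                       batch_size = 12, dropout = 0, l2 = 0, seed = 5)
  cfg1 <- cvcnn_config(conv_channels = 4, fc_widths = c(8, 2), epochs = 1,
                       batch_size = 12, dropout = 0, l2 = 0.5, seed = 5)
  m0 <- cvcnn_train(d, cfg0)
  m1 <- cvcnn_train(d, cfg1)
  # identical seed: the only difference is the decay term on conv weights
  expect_false(isTRUE(all.equal(m0$layers[[1]]$wre, m1$layers[[1]]$wre)))
  lr <- cfg0$lr
  # fc weights and biases are identical; conv update differs by lr*l2*w
  expect_equal(m0$layers[[2]]$wre, m1$layers[[2]]$wre, tolerance = 1e-4)
  expect_equal(m0$layers[[1]]$bre, m1$layers[[1]]$bre, tolerance = 1e-10)
})

test_that("training separates a linearly separable complex toy set", {
  # two classes that differ only in the phase of their pixels
  set.seed(21)
  g <- frequency_grid()
  mk <- function(lab, ph, n) {
    purrr::map(seq_len(n), function(i) {
      s <- matrix(runif(100, 0.2, 0.8), 10, 10)
      a <- matrix(cvpac:::wrap_phase(ph + rnorm(100, 0, 0.3)), 10, 10)
      cvpac:::new_cvpac_image(matrix(complex(modulus = s, argument = a),
                                     10, 10), g, list(label = lab))
    })
  }
  imgs <- c(mk("normal", -2, 30), mk("pathological", 1, 30))
  labs <- rep(c("normal", "pathological"), each = 30)
  cfg <- cvcnn_config(conv_channels = 4, fc_widths = c(8, 2), epochs = 40,
                      batch_size = 20, lr = 0.05, dropout = 0, l2 = 0,
                      seed = 2)
  m <- cvcnn_train(list(images = imgs, labels = labs), cfg)
  # smoothed loss decreases and ends near zero
  lo <- m$training_log$loss
  sm <- stats::filter(lo, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(utils::tail(sm, 1), utils::head(sm, 1) / 4)
  p <- predict(m, imgs)
  expect_equal(mean((p > 0.5) == (labs == "pathological")), 1)
})

test_that("training and prediction are deterministic given the seed", {
  d <- tiny_dataset(n_per_class = 6, windows_per_channel = 3,
                    patients = "A", seed = 31)
  cfg <- cvcnn_config(conv_channels = 4, fc_widths = c(8, 2), epochs = 3,
                      batch_size = 8, seed = 9)
  m1 <- cvcnn_train(d, cfg)
  m2 <- cvcnn_train(d, cfg)
  expect_identical(m1$training_log$loss, m2$training_log$loss)
  expect_identical(predict(m1, d)$prob_pathological,
                   predict(m2, d)$prob_pathological)
  # probabilities are a softmax: in [0,1], duplicates map identically
  p <- predict(m1, d)$prob_pathological
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p[1], predict(m1, d[1, ])$prob_pathological)
  # single-class data is rejected
  expect_error(cvcnn_train(d[d$label == "normal", ], cfg), "single class")
})

test_that("two-layer and strength representations expose the right parts", {
  d <- tiny_dataset(n_per_class = 2, windows_per_channel = 2,
                    patients = "A", seed = 41)
  arr <- to_two_layer_real(d$image)
  expect_equal(dim(arr), c(10, 10, 2, 4))
  expect_equal(arr[, , 1, 2], Re(d$image[[2]]$pixels))
  expect_equal(arr[, , 2, 2], Im(d$image[[2]]$pixels))
  # round trip to complex
  expect_equal(arr[, , 1, 3] + 1i * arr[, , 2, 3], d$image[[3]]$pixels)
  s <- to_two_layer_real(d$image, "strength")
  expect_equal(dim(s), c(10, 10, 1, 4))
  expect_equal(s[, , 1, 1], Mod(d$image[[1]]$pixels))
  # purely real image -> zero imaginary channel
  ri <- d$image[[1]]
  ri$pixels <- matrix(complex(real = Re(ri$pixels)), 10, 10)
  expect_equal(max(abs(to_two_layer_real(list(ri))[, , 2, 1])), 0)
})

test_that("analytic gradients match numerical differentiation", {
  for (setup in list(list(rep = "complex", bn = "per_part"),
                     list(rep = "complex", bn = "whiten"),
                     list(rep = "two_layer", bn = "per_part"))) {
    cfg <- cvcnn_config(conv_channels = c(2, 3), kernel = 3,
                        fc_widths = c(5, 2), dropout = 0, l2 = 0,
                        representation = setup$rep, bn_mode = setup$bn,
                        seed = 7)
    C <- if (setup$rep == "two_layer") 2L else 1L
    set.seed(7)
    model <- cvpac:::init_cvcnn(cfg, c(6, 6, C))
    N <- 5
    xre <- array(rnorm(6 * 6 * C * N, sd = .5), c(6, 6, C, N))
    xim <- if (cfg$field == "complex") {
      array(rnorm(6 * 6 * C * N, sd = .5), c(6, 6, C, N))
    } else array(0, c(6, 6, C, N))
    mre <- cvpac:::to_mat(xre)
    mim <- cvpac:::to_mat(xim)
    y <- c(1, 2, 1, 2, 2)
    lossfun <- function(m) {
      fw <- cvpac:::net_forward(m, mre, mim, training = TRUE)
      cvpac:::softmax_xent(fw$logits, y)$loss
    }
    fw <- cvpac:::net_forward(model, mre, mim, training = TRUE)
    sx <- cvpac:::softmax_xent(fw$logits, y)
    gr <- cvpac:::net_backward(model, fw, sx$dlogits)
    pars <- cvpac:::cvcnn_flatten(model)
    for (nm in names(pars)) {
      if (cfg$field == "real" && grepl("im", nm)) next
      f <- function(v) {
        p <- pars; pp <- pars[[nm]]; pp[] <- v; p[[nm]] <- pp
        lossfun(cvpac:::cvcnn_restore(model, p))
      }
      ng <- numgrad(f, pars[[nm]])
      li <- sub("\\..*", "", nm)
      pn <- sub(".*\\.", "", nm)
      ag <- if (li == "RO") gr$readout[[paste0("d", pn)]] else {
        gr$layers[[as.integer(sub("L", "", li))]][[paste0("d", pn)]]
      }
      expect_lt(max(abs(ng - ag)) / max(1, max(abs(ng))), 1e-4)
    }
  }
})
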