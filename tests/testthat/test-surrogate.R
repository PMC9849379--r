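test_that("strong simulated coupling survives the surrogate screen", {
  x <- coupled_window(f_low = 2.5, f_high = 100, d = 1, phase = 0,
                      noise_sd = 0.2, seed = 21)
  raw <- cvpac_image(x, 1000, pad = c(2000, 2000))
  st <- st_cvpac_image(x, 1000, pad = c(2000, 2000), seed = 22)
  s <- coupling_strengths(raw)
  top <- arrayInd(which.max(s), dim(s))
  expect_gt(Mod(st$pixels[top]), 0)                 # retained
  expect_equal(st$pixels[top], raw$pixels[top])     # unchanged, not rescaled
  # screening only zeroes pixels, never alters survivors
  kept <- Mod(st$pixels) > 0
  expect_equal(st$pixels[kept], raw$pixels[kept])
  expect_equal(st$provenance$n_retained, sum(kept))
})

test_that("null retention on uncoupled noise is calibrated near alpha", {
  # 20 windows x 100 pixels; exact null retention of the rule is
  # 5/101 per pixel, so check the 99% binomial band around it
  set.seed(55)
  n_win <- 20
  ret <- 0
  for (i in seq_len(n_win)) {
    st <- st_cvpac_image(rnorm(14000), 1000, pad = c(2000, 2000),
                         n_shuffles = 100, alpha = 0.05, seed = 900 + i)
    ret <- ret + st$provenance$n_retained
  }
  rate <- ret / (n_win * 100)
  p0 <- 5 / 101
  half <- 2.576 * sqrt(p0 * (1 - p0) / (n_win * 100))
  expect_gt(rate, p0 - half - 0.015)   # slack for within-window correlation
  expect_lt(rate, p0 + half + 0.015)
})

test_that("alpha extremes behave per contract", {
  x <- coupled_window(seed = 3, rate = 500)
  st1 <- st_cvpac_image(x, 500, pad = c(1000, 1000), alpha = 1, seed = 1)
  expect_true(all(st1$pixels == 0))
  expect_equal(st1$provenance$n_retained, 0L)
  expect_error(st_cvpac_image(x, 500, alpha = 0), "alpha")
  expect_error(st_cvpac_image(x, 500, alpha = -0.1), "alpha")
  expect_error(st_cvpac_image(x, 500, n_shuffles = 10), "at least 20")
  expect_error(st_cvpac_image(x, 500, n_shuffles = 50, alpha = 0.01),
               "at least 1")
})

test_that("surrogate screening is reproducible given a seed", {
  x <- coupled_window(d = 0.5, seed = 8, rate = 500)
  a <- st_cvpac_image(x, 500, pad = c(1000, 1000), seed = 77)
  b <- st_cvpac_image(x, 500, pad = c(1000, 1000), seed = 77)
  c <- st_cvpac_image(x, 500, pad = c(1000, 1000), seed = 78)
  expect_identical(a$pixels, b$pixels)
  # a different seed may flip borderline pixels but keeps the strong ones;
  # determinism is about identical seeds, so only assert a difference in
  # the RNG stream was possible, not required
  expect_s3_class(c, "cvpac_image")
})

test_that("full-permutation mode runs and is anti-conservative on noise", {
  set.seed(91)
  x <- rnorm(7000)
  shift <- st_cvpac_image(x, 500, pad = c(1000, 1000), seed = 5,
                          method = "shift")
  perm <- st_cvpac_image(x, 500, pad = c(1000, 1000), seed = 5,
                         method = "permute")
  # the permutation null ignores serial correlation: it retains far more
  # noise pixels than the calibrated circular-shift null
  expect_gt(perm$provenance$n_retained, shift$provenance$n_retained)
})

test_that("surrogate_cvpac screens a windows table with child seeds", {
  w <- noise_windows(3, rate = 400, seed = 13)
  d1 <- surrogate_cvpac(w, seed = 99)
  d2 <- surrogate_cvpac(w, seed = 99)
  expect_identical(purrr::map(d1$image, "pixels"),
                   purrr::map(d2$image, "pixels"))
  expect_true(all(purrr::map_int(d1$image,
                                 ~ .x$provenance$n_retained) <= 100))
})
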