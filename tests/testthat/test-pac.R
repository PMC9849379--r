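test_that("phase-amplitude distribution normalizes and localizes mass", {
  set.seed(1)
  ph <- runif(20000, -pi, pi)
  # constant amplitude -> uniform distribution
  d <- phase_amplitude_distribution(ph, rep(3.7, length(ph)))
  expect_equal(sum(d$p), 1, tolerance = 1e-12)
  expect_equal(d$p, rep(1 / 18, 18), tolerance = 1e-12)
  # all mass in bin 5 -> one-hot
  bins <- cvpac:::phase_bin_index(ph, 18)
  amp <- as.numeric(bins == 5)
  d5 <- phase_amplitude_distribution(ph, amp)
  expect_equal(d5$p[5], 1)
  expect_equal(sum(d5$p[-5]), 0)
  # amplitude 1 + cos(phase): P matches the discretized profile
  bc <- cvpac:::phase_bin_centers(18)
  # closed-form bin integral of (1 + cos) over each bin, normalized
  w <- pi / 9
  ints <- sapply(bc, function(c0) {
    w + 2 * sin(w / 2) * cos(c0)
  })
  d2 <- phase_amplitude_distribution(ph, 1 + cos(ph))
  expect_equal(d2$p, ints / sum(ints), tolerance = 0.01)
})

test_that("empty phase bins are flagged or rejected per policy", {
  ph <- runif(500, 0, 1)   # covers only part of one cycle
  amp <- rep(1, 500)
  d <- phase_amplitude_distribution(ph, amp)
  expect_true("empty_bin" %in% d$flags)
  expect_equal(sum(d$p), 1)
  expect_error(phase_amplitude_distribution(ph, amp, empty_bin = "reject"),
               "no samples")
})

test_that("KL distance to uniform matches the summation oracle", {
  # fixed examples
  expect_equal(kl_to_uniform(rep(1 / 18, 18)), 0)
  expect_equal(kl_to_uniform(c(1, rep(0, 17))), log(18))
  expect_equal(kl_to_uniform(c(0.5, 0.5, rep(0, 16))), log(9))
  # oracle equivalence on random simplex vectors
  set.seed(7)
  for (i in 1:1000) {
    p <- rsimplex(18)
    expect_equal(kl_to_uniform(p), kl_oracle(p), tolerance = 1e-10)
  }
  expect_error(kl_to_uniform(rep(0.1, 18)), "not normalized")
})

test_that("modulation index attains its bounds and stays in [0, 1]", {
  expect_identical(modulation_index(rep(1 / 18, 18)), 0)
  expect_equal(modulation_index(c(rep(0, 9), 1, rep(0, 8))), 1)
  expect_equal(modulation_index(c(0.5, 0.5, rep(0, 16))), log(9) / log(18))
  set.seed(11)
  s <- replicate(2000, modulation_index(rsimplex(18)))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("coupling phase picks the peak bin center with low-index ties", {
  bc <- cvpac:::phase_bin_centers(18)
  one_hot <- function(j) { p <- rep(0, 18); p[j] <- 1; p }
  expect_equal(coupling_phase(one_hot(10)), bc[10])  # bin centered near 0+
  # peak of 1 + cos(phase - pi/2) lies within one bin of pi/2
  set.seed(3)
  ph <- runif(50000, -pi, pi)
  d <- phase_amplitude_distribution(ph, 1 + cos(ph - pi / 2))
  expect_lte(circ_diff(coupling_phase(d), pi / 2), pi / 9)
  # uniform: tie broken toward the lowest bin index
  expect_equal(coupling_phase(rep(1 / 18, 18)), bc[1])
})

test_that("cvpac_pixel is the polar-to-cartesian map with bounded modulus", {
  expect_equal(cvpac_pixel(1, 0), 1 + 0i)
  expect_equal(cvpac_pixel(0.5, pi / 2), 0 + 0.5i)
  z <- cvpac_pixel(log(9) / log(18), -pi / 3)
  expect_equal(Re(z), log(9) / log(18) * cos(-pi / 3), tolerance = 1e-12)
  expect_equal(Im(z), log(9) / log(18) * sin(-pi / 3), tolerance = 1e-12)
  expect_equal(Mod(z), log(9) / log(18))
  expect_equal(Arg(z), -pi / 3)
  # zero strength stores exactly 0
  expect_identical(cvpac_pixel(0, 2.3), 0 + 0i)
  expect_error(cvpac_pixel(1.2, 0), "\\[0, 1\\]")
  # vectorized round trip
  set.seed(5)
  s <- runif(50); a <- runif(50, -pi, pi)
  z <- cvpac_pixel(s, a)
  expect_equal(Mod(z), s)
  expect_equal(Arg(z)[s > 0], a[s > 0])
})
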