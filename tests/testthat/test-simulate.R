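test_that("coupled-signal generation is seed-deterministic", {
  comp <- data.frame(f_low = 4, f_high = 60, strength = 0.6, phase = 1)
  a <- generate_coupled_signal(comp, 5, 500, seed = 10)
  b <- generate_coupled_signal(comp, 5, 500, seed = 10)
  c <- generate_coupled_signal(comp, 5, 500, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_length(a, 5 * 500)
  expect_error(generate_coupled_signal(
    data.frame(f_low = 4, f_high = 300, strength = .5, phase = 0), 5, 500),
    "rate")
})

test_that("measured coupling strength increases monotonically with depth", {
  g <- frequency_grid()
  row <- findInterval(100, g$high_edges)
  col <- findInterval(2.5, g$low_edges)
  ds <- seq(0.1, 0.9, by = 0.2)
  mean_s <- sapply(ds, function(d) {
    mean(sapply(1:3, function(s) {
      x <- coupled_window(f_low = 2.5, f_high = 100, d = d, phase = 0,
                          noise_sd = 0.3, rate = 500, seed = 100 * s + d * 10)
      img <- cvpac_image(x, 500, pad = c(1000, 1000))
      coupling_strengths(img)[row, col]
    }))
  })
  expect_equal(cor(mean_s, ds, method = "spearman"), 1)
  # no modulation -> strength at noise level
  x0 <- coupled_window(d = 0, noise_sd = 0.3, rate = 500, seed = 3)
  img0 <- cvpac_image(x0, 500, pad = c(1000, 1000))
  expect_lt(coupling_strengths(img0)[row, col], 0.01)
})

test_that("specified coupled phase is recovered within one bin", {
  g <- frequency_grid()
  row <- findInterval(100, g$high_edges)
  col <- findInterval(2.5, g$low_edges)
  # target phases on bin centers, so bin quantization cannot straddle edges
  bc <- cvpac:::phase_bin_centers(18)
  for (ph in bc[c(3, 8, 13, 17)]) {
    x <- coupled_window(f_low = 2.5, f_high = 100, d = 0.8, phase = ph,
                        noise_sd = 0.3, rate = 500, seed = round(ph * 7) + 50)
    img <- cvpac_image(x, 500, pad = c(1000, 1000))
    expect_lte(circ_diff(coupling_phases(img)[row, col], ph), pi / 9 + 1e-9)
  }
})

test_that("simulated window tables have channel structure and balance", {
  w <- simulate_windows(n_per_class = 10, windows_per_channel = 5,
                        rate = 400, seed = 6)
  expect_equal(nrow(w), 20)
  expect_equal(sum(w$label == "pathological"), 10)
  expect_equal(length(unique(w$channel)), 4)
  expect_true(all(table(w$channel) == 5))
  expect_true(all(lengths(w$samples) == (10 + 4) * 400))
  # imbalance option
  wi <- simulate_windows(n_per_class = 10, windows_per_channel = 5,
                         rate = 400, imbalance_ratio = 1 / 2.5, seed = 6)
  expect_equal(sum(wi$label == "normal"), 10)
  expect_equal(sum(wi$label == "pathological"), 4)
  # empty dataset
  expect_equal(nrow(generate_labeled_dataset(n_per_class = 0, seed = 1)), 0)
})

test_that("labeled datasets are bit-identical under a fixed seed", {
  d1 <- generate_labeled_dataset(n_per_class = 4, windows_per_channel = 2,
                                 rate = 400, seed = 14)
  d2 <- generate_labeled_dataset(n_per_class = 4, windows_per_channel = 2,
                                 rate = 400, seed = 14)
  expect_identical(purrr::map(d1$image, "pixels"),
                   purrr::map(d2$image, "pixels"))
})

test_that("phase-only classes differ in phase but not in strength", {
  d <- generate_labeled_dataset(default_class_specs("phase_only"),
                                n_per_class = 24, windows_per_channel = 4,
                                rate = 500, seed = 20)
  s_mean <- purrr::map_dbl(d$image, ~ mean(coupling_strengths(.x)))
  p <- stats::wilcox.test(s_mean[d$label == "pathological"],
                          s_mean[d$label == "normal"])$p.value
  expect_gt(p, 0.01)   # strength summaries indistinguishable
  # coupled phases differ: circular mean of the alpha-band pixels separates
  # the classes even though strengths do not
  g <- d$image[[1]]$grid
  acol <- which(g$low_centers >= 8)
  zphase <- function(lab) {
    Arg(sum(vapply(d$image[d$label == lab],
                   function(im) sum(im$pixels[, acol]), complex(1))))
  }
  expect_gt(circ_diff(zphase("pathological"), zphase("normal")), 1)
})

test_that("cohort simulation runs the full pipeline with correct counts", {
  cohort <- tibble::tibble(patient = c("Q1", "Q2"),
                           durations = list(c(24, 16), 30))
  w <- simulate_cohort(cohort, n_pairs = 2, n_pathological = 1, rate = 400,
                       seed = 33)
  # per channel: (24,16) -> 8+4 windows; 30 -> 11 windows
  expect_equal(sum(w$patient == "Q1"), 2 * (8 + 4))
  expect_equal(sum(w$patient == "Q2"), 2 * 11)
  expect_setequal(unique(w$label), c("pathological", "normal"))
  # bipolar labels look like anode-cathode
  expect_true(all(grepl("^E\\d+-E\\d+$", w$channel)))
  expect_equal(attr(w, "rate"), 400)
})
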