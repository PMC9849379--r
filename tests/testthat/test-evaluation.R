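fake_predictions <- function(fracs_pos, fracs_neg, n_win = 20) {
  # build a window-level prediction table whose channel fractions are exact
  mk <- function(fracs, truth, tag) {
    purrr::imap_dfr(fracs, function(f, i) {
      k <- round(f * n_win)
      tibble::tibble(patient = "P", channel = paste0(tag, i),
                     label = if (truth) "pathological" else "normal",
                     prob_pathological = rep(c(0.9, 0.1),
                                             c(k, n_win - k)))
    })
  }
  dplyr::bind_rows(mk(fracs_pos, TRUE, "pos"), mk(fracs_neg, FALSE, "neg"))
}

test_that("channel scores count pathological window votes", {
  pred <- tibble::tibble(patient = "P", channel = "A",
                         label = "pathological",
                         prob_pathological = c(rep(.8, 3), rep(.2, 26)))
  sc <- channel_scores(pred)
  expect_equal(sc$pathological_fraction, 3 / 29)
  expect_equal(sc$n_windows, 29)
  expect_true(sc$truth)
  # all windows pathological -> fraction 1
  pred$prob_pathological <- 0.7
  expect_equal(channel_scores(pred)$pathological_fraction, 1)
  # permutation invariance
  pred2 <- fake_predictions(c(.3, .6), c(.1), n_win = 10)
  sc1 <- channel_scores(pred2)
  sc2 <- channel_scores(pred2[sample.int(nrow(pred2)), ])
  expect_equal(dplyr::arrange(sc1, channel), dplyr::arrange(sc2, channel))
  # mean_prob rule averages probabilities instead of votes
  scm <- channel_scores(pred, "mean_prob")
  expect_equal(scm$pathological_fraction, 0.7)
})

test_that("ROC attains 1 on separated scores and 0.5 on permuted truth", {
  sc <- channel_scores(fake_predictions(c(.7, .8, .9), c(.1, .2, .3)))
  r <- roc_auc(sc)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity_at_optimal, 1)
  expect_equal(r$specificity_at_optimal, 1)
  # permuted truth at large n -> AUC near 1/2
  set.seed(5)
  big <- tibble::tibble(pathological_fraction = runif(2000),
                        truth = sample(c(TRUE, FALSE), 2000, replace = TRUE))
  expect_equal(roc_auc(big)$auc, 0.5, tolerance = 0.05)
  expect_error(roc_auc(tibble::tibble(pathological_fraction = 1:3 / 3,
                                      truth = c(TRUE, TRUE, TRUE))),
               "both truth classes")
})

test_that("threshold-sweep AUC equals the rank-statistic oracle", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    x <- round(runif(n), sample(c(1, 2, 7), 1))  # force ties sometimes
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    sc <- tibble::tibble(pathological_fraction = x, truth = y)
    expect_equal(roc_auc(sc)$auc, auc_rank_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("our ROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  x <- runif(60)
  y <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  ours <- roc_auc(tibble::tibble(pathological_fraction = x, truth = y))
  ref <- pROC::roc(response = y, predictor = x, quiet = TRUE,
                   direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("Youden threshold is consistent with its confusion matrix", {
  set.seed(29)
  x <- runif(40)
  y <- x + rnorm(40, 0, 0.3) > 0.5
  if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
  r <- roc_auc(tibble::tibble(pathological_fraction = x, truth = y))
  t0 <- r$optimal_threshold
  expect_equal(r$sensitivity_at_optimal, mean(x[y] > t0))
  expect_equal(r$specificity_at_optimal, mean(x[!y] <= t0))
  j <- r$curve$sensitivity + r$curve$specificity - 1
  expect_equal(max(j), r$sensitivity_at_optimal +
                 r$specificity_at_optimal - 1)
})

test_that("LOOCV isolates the held-out patient and reports per patient", {
  d <- tiny_dataset(n_per_class = 6, windows_per_channel = 3,
                    patients = c("A", "B"), seed = 61)
  seen <- new.env()
  cfg <- cvcnn_config(conv_channels = 2, fc_widths = 2, epochs = 1,
                      batch_size = 8, seed = 1)
  res <- loocv(d, "cvcnn", cfg)
  expect_s3_class(res, "loocv_result")
  expect_equal(sort(res$by_patient$patient), c("A", "B"))
  expect_equal(nrow(res$by_patient), 2)
  expect_true(all(res$by_patient$auc >= 0 & res$by_patient$auc <= 1,
                  na.rm = TRUE))
  expect_equal(res$mean_auc, mean(res$by_patient$auc, na.rm = TRUE))
  # isolation: a transform hook sees disjoint train/test window sets
  loocv(d, "rf", cfg, transform_images = function(train, test) {
    expect_length(intersect(train$window_id, test$window_id), 0)
    expect_length(unique(test$patient), 1)
    expect_false(unique(test$patient) %in% train$patient)
    assign("ran", TRUE, envir = seen)
    list(train = train, test = test)
  })
  expect_true(get("ran", envir = seen))
  expect_error(loocv(d[d$patient == "A", ], "rf"), "2 patients")
})

test_that("identical patients give identical per-round AUCs", {
  d1 <- tiny_dataset(n_per_class = 6, windows_per_channel = 3,
                     patients = "A", seed = 71)
  d2 <- d1
  d2$patient <- "B"
  d2$channel <- sub("^A_", "B_", d2$channel)
  d <- dplyr::bind_rows(d1, d2)
  res <- loocv(d, "rf", cvcnn_config_small(representation = "two_layer"))
  expect_equal(res$by_patient$auc[1], res$by_patient$auc[2])
})

test_that("SVM and RF baselines run end-to-end on image features", {
  d <- tiny_dataset(n_per_class = 8, windows_per_channel = 4,
                    patients = c("A", "B"), seed = 81)
  rf <- baseline(d, "rf", "two_layer")
  expect_s3_class(rf, "loocv_result")
  expect_equal(nrow(rf$by_patient), 2)
  sv <- baseline(d, "svm", "strength",
                 svm_params = list(cost = 4, gamma = 0.01))
  expect_true(is.finite(sv$mean_auc))
  # glance/tidy accessors
  expect_equal(nrow(tidy(rf)), 2)
  expect_equal(glance(rf)$method, "rf")
})

test_that("SVM grid search returns the argmax pair of the grid", {
  d <- tiny_dataset(n_per_class = 8, windows_per_channel = 4,
                    patients = c("A", "B"), seed = 91)
  gs <- svm_grid_search(d[d$patient == "A", ], d[d$patient == "B", ],
                        costs = c(1, 16), gammas = c(0.01, 1),
                        representation = "two_layer")
  expect_equal(nrow(gs$results), 4)
  best <- gs$results[which.max(gs$results$auc), ]
  expect_equal(gs$cost, best$cost)
  expect_equal(gs$gamma, best$gamma)
  expect_equal(gs$auc, best$auc)
})

test_that("ablating a band uses training-split moments and reruns LOOCV", {
  d <- tiny_dataset(n_per_class = 6, windows_per_channel = 3,
                    patients = c("A", "B"), seed = 101)
  ref <- loocv(d, "rf", cvcnn_config_small(representation = "two_layer"))
  ab <- run_ablation_experiment(d, "slow_delta", method = "rf",
                                config = cvcnn_config_small(
                                  representation = "two_layer"),
                                seed = 4, reference = ref)
  expect_equal(ab$band, "slow_delta")
  expect_equal(ab$reference_auc, ref$mean_auc)
  expect_equal(ab$auc_drop, ref$mean_auc - ab$mean_auc)
  expect_s3_class(ab$loocv, "loocv_result")
})

test_that("row-restricted datasets feed the evaluation unchanged", {
  d <- tiny_dataset(n_per_class = 4, windows_per_channel = 2,
                    patients = c("A", "B"), seed = 111)
  dg <- restrict_dataset(d, "gamma")
  expect_true(all(purrr::map_int(dg$image, ~ nrow(.x$pixels)) < 10))
  res <- loocv(dg, "rf", cvcnn_config_small(representation = "two_layer"))
  expect_s3_class(res, "loocv_result")
})
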