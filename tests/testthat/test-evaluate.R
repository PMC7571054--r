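test_that("thresholding follows the >= tie rule and its extremes", {
  probs <- matrix(0.5, 4, 4)
  expect_true(all(threshold_map(probs, 0.5) == 1L))
  expect_true(all(threshold_map(probs, 0) == 1L))
  expect_true(all(threshold_map(probs, 0.500001) == 0L))
  expect_equal(formals(threshold_map)$threshold, 0.5)
  expect_error(threshold_map(probs, 1.5), "\\[0, 1\\]")
})

test_that("precision and recall match brute-force confusion counting", {
  truth <- matrix(0L, 4, 4); truth[, 1:2] <- 1L
  allp <- matrix(1L, 4, 4)
  pr <- precision_recall(allp, truth)
  expect_equal(unname(pr), c(0.5, 1))

  expect_equal(unname(precision_recall(truth, truth)), c(1, 1))
  # degenerate conventions
  none <- matrix(0L, 4, 4)
  expect_equal(unname(precision_recall(none, truth)), c(1, 0))
  expect_equal(unname(precision_recall(truth, none)), c(0, 1))
  expect_equal(unname(precision_recall(none, none)), c(1, 1))

  set.seed(21)
  for (i in 1:20) {
    pred <- matrix(rbinom(64, 1, 0.4), 8, 8)
    tru <- matrix(rbinom(64, 1, 0.3), 8, 8)
    expect_equal(precision_recall(pred, tru),
                 brute_precision_recall(pred, tru))
  }
  expect_error(precision_recall(matrix(0, 2, 2), matrix(0, 3, 3)),
               "same shape")
})

test_that("the F-measure is the harmonic mean with a zero convention", {
  expect_equal(f_measure(1, 1), 1)
  expect_equal(f_measure(0.5, 1), 0.6667, tolerance = 1e-4)
  expect_equal(f_measure(0, 0), 0)
  expect_equal(f_measure(0.3, 0.7), 2 * 0.3 * 0.7 / (0.3 + 0.7))
})

test_that("the Pratt Figure of Merit matches hand and brute-force evaluation", {
  truth <- matrix(0L, 5, 5); truth[, 3] <- 1L
  expect_equal(pratt_fom(truth, truth), 1)

  # prediction shifted one column: d = 1 for all 5 points, a = 1/9
  shifted <- matrix(0L, 5, 5); shifted[, 4] <- 1L
  expect_equal(pratt_fom(shifted, truth), 5 * (1 / (1 + 1 / 9)) / 5)
  expect_equal(pratt_fom(shifted, truth), 0.9)

  none <- matrix(0L, 5, 5)
  expect_equal(pratt_fom(none, truth), 0)
  expect_equal(pratt_fom(truth, none), 0)
  expect_equal(pratt_fom(none, none), 1)

  # all 2^9 predicted patterns of a 3x3 map against a fixed truth
  truth3 <- matrix(c(0, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3)
  for (code in 0:511) {
    pred <- matrix(as.integer(intToBits(code)[1:9]), 3, 3)
    expect_equal(pratt_fom(pred, truth3), brute_pratt(pred, truth3),
                 tolerance = 1e-12)
    expect_equal(precision_recall(pred, truth3),
                 brute_precision_recall(pred, truth3))
  }
})

test_that("recall never increases with the threshold", {
  set.seed(17)
  thresholds <- seq(0, 1, length.out = 21)
  for (i in 1:10) {
    probs <- matrix(runif(64), 8, 8)
    truth <- matrix(rbinom(64, 1, 0.3), 8, 8)
    rec <- sapply(thresholds, function(th)
      precision_recall(threshold_map(probs, th), truth)["recall"])
    expect_true(all(diff(rec) <= 1e-12))
  }
})

test_that("test-set evaluation handles oracle, constant and single-image cases", {
  set.seed(23)
  lib <- small_proc_library()
  samples <- lapply(1:5, function(i) {
    s <- generate_mosaic(c(32, 32), lib, augment_config(enabled = FALSE),
                         seed = 40 + i)
    list(image = s$image, mask = s$target$mask)
  })

  # oracle emitting the ground truth as {0,1} probabilities
  k <- 0
  oracle <- function(img) {
    k <<- k + 1
    samples[[k]]$mask + 0
  }
  rep_oracle <- evaluate_testset(oracle, samples)
  expect_equal(rep_oracle$auc_pr, 1)
  expect_equal(rep_oracle$max_mean_f, 1)
  expect_equal(rep_oracle$max_mean_fom, 1)
  expect_equal(rep_oracle$n_images, 5L)
  expect_equal(nrow(rep_oracle$curves), 101L)
  with(rep_oracle$curves, {
    expect_true(all(precision >= 0 & precision <= 1))
    expect_true(all(recall >= 0 & recall <= 1))
    expect_true(all(f_measure >= 0 & f_measure <= 1))
    expect_true(all(fom >= 0 & fom <= 1))
  })

  # constant 0.5 predictor: below the tie point everything is border
  rep_const <- evaluate_testset(function(img) matrix(0.5, 32, 32),
                                samples)
  border_frac <- mean(sapply(samples, function(s) mean(s$mask)))
  low <- rep_const$curves$threshold <= 0.5
  expect_true(all(rep_const$curves$recall[low] == 1))
  expect_equal(rep_const$curves$precision[low],
               rep(border_frac, sum(low)))

  # macro average over one image equals the single-image metrics
  one <- samples[1]
  probs <- matrix(runif(32 * 32), 32, 32)
  rep_one <- evaluate_testset(function(img) probs, one,
                              thresholds = c(0.25, 0.5, 0.75))
  for (j in 1:3) {
    pr <- precision_recall(threshold_map(probs, c(0.25, 0.5, 0.75)[j]),
                           one[[1]]$mask)
    expect_equal(rep_one$curves$precision[j], unname(pr["precision"]))
    expect_equal(rep_one$curves$recall[j], unname(pr["recall"]))
    expect_equal(rep_one$curves$fom[j],
                 pratt_fom(threshold_map(probs, c(0.25, 0.5, 0.75)[j]),
                           one[[1]]$mask))
  }
  expect_error(evaluate_testset(oracle, list()), "empty")
  expect_error(evaluate_testset(oracle, samples, thresholds = c(0.5, 0.5)),
               "strictly increasing")
})
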