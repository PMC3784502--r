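# Calibration: objective properties, behavioural anchors, and parameter
# recovery from synthetic data.

test_that("the objective is zero at the targets, quadratic, and order-invariant", {
  tg <- default_targets()
  beh <- c(ss_bcat = 35, halflife_wt = 1800, halflife_mutant = 16200,
           halflife_phospho = 600)
  p <- default_parameters()
  expect_equal(objective(p, tg, behaviours = beh), 0)
  # doubling one residual quadruples its contribution
  b1 <- beh; b1["ss_bcat"] <- 35 * 1.1
  b2 <- beh; b2["ss_bcat"] <- 35 * 1.2
  l1 <- objective(p, tg, behaviours = b1)
  l2 <- objective(p, tg, behaviours = b2)
  expect_equal(l2 / l1, 4, tolerance = 1e-9)
  # order invariance
  expect_equal(objective(p, rev(tg), behaviours = beh[c(3, 1, 4, 2)]),
               objective(p, tg, behaviours = beh))
  # dropping a target can only reduce the loss
  bh <- beh * c(1.05, 1.1, 0.9, 1.02)
  expect_lte(objective(p, tg[-2], behaviours = bh[-2]),
             objective(p, tg, behaviours = bh))
})

test_that("the calibrated defaults meet all four behavioural targets", {
  beh <- model_behaviours(default_parameters())
  expect_equal(beh[["ss_bcat"]], 35, tolerance = 0.02)
  expect_equal(beh[["halflife_wt"]], 1800, tolerance = 0.20)
  expect_equal(beh[["halflife_mutant"]], 16200, tolerance = 0.20)
  expect_equal(beh[["halflife_phospho"]], 600, tolerance = 0.02)
})

test_that("one-parameter fits recover the truth from noiseless decay data", {
  truth <- default_parameters()$kdeg_slow
  ds <- gen_decay(cv = 0, mutant = TRUE)
  start <- default_parameters(list(kdeg_slow = truth * 5))
  fit <- fit_parameters("kdeg_slow", targets = NULL, dataset = ds,
                        params = start, n_starts = 3L, seed = 2L)
  expect_equal(fit$params$kdeg_slow, truth, tolerance = 0.01)
  # parameters not listed free are untouched
  expect_identical(fit$params$kp_bcat, start$kp_bcat)
  expect_identical(fit$params$chi, start$chi)
  expect_s3_class(fit, "dcx_fit")
  expect_named(coef(fit), "kdeg_slow")
})

test_that("recovery from noisy decay data meets the study thresholds", {
  rec0 <- recovery_study(cv = 0, n_replicates = 3L, seed = 300L)
  expect_lt(rec0$median_rel_error, 0.02)
  rec <- recovery_study(cv = 0.05, n_replicates = 20L, seed = 500L)
  expect_gte(rec$frac_within_25pct, 0.8)
})

test_that("the dataset loss is consistent with its model predictor", {
  ds <- gen_decay(cv = 0.05, seed = 9, mutant = TRUE)
  p <- default_parameters()
  pred <- predict_dataset(p, ds)
  expect_equal(pred, exp(-p$kdeg_slow * ds$design))
  # loss at truth below loss at a 3x-off parameter value
  l_true <- dcx:::dataset_loss(p, ds)
  l_off <- dcx:::dataset_loss(set_parameters(p, list(kdeg_slow = 3 * p$kdeg_slow)), ds)
  expect_lt(l_true, l_off)
})
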