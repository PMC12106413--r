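test_that("weighted fusion is an elementwise convex combination", {
  y1 <- c(2, 4, 6); y2 <- c(4, 2, 0)
  expect_equal(weighted_fusion(list(y1, y2), c(1, 0)), y1)
  expect_equal(weighted_fusion(list(y1, y2), c(0.5, 0.5)), c(3, 3, 3))
  preds <- phytofuse:::with_seed(1, replicate(3, stats::rnorm(10), simplify = FALSE))
  w <- c(0.2, 0.5, 0.3)
  by_hand <- w[1] * preds[[1]] + w[2] * preds[[2]] + w[3] * preds[[3]]
  expect_equal(weighted_fusion(preds, w), by_hand, tolerance = 1e-12)
  expect_error(weighted_fusion(list(y1, y2), c(0.5, 0.4)), "sum to 1")
  expect_error(weighted_fusion(list(c(1, 2), c(1, 2, 3)), c(0.5, 0.5)), "equal length")
})

test_that("weight optimization matches the simplex grid-search oracle", {
  dat <- phytofuse:::with_seed(5, {
    y1 <- stats::rnorm(200)
    y2 <- stats::rnorm(200)
    list(y1 = y1, y2 = y2, truth = 0.3 * y1 + 0.7 * y2)
  })
  w <- optimize_weights(cbind(a = dat$y1, b = dat$y2), dat$truth)
  expect_equal(as.numeric(w), c(0.3, 0.7), tolerance = 0.01)
  oracle <- grid_search_weights(cbind(dat$y1, dat$y2), dat$truth, step = 0.01)
  expect_lte(attr(w, "mse"), oracle$mse + 1e-12)

  # a perfect module dominates a noisy one
  noisy <- dat$truth + phytofuse:::with_seed(6, stats::rnorm(200, sd = 0.5))
  w2 <- optimize_weights(cbind(exact = dat$truth, noisy = noisy), dat$truth)
  expect_gte(as.numeric(w2)[1], 0.95)
})

test_that("optimized weights never lose to any single module", {
  for (seed in 1:8) {
    dat <- phytofuse:::with_seed(seed, {
      truth <- stats::rnorm(80)
      P <- sapply(1:3, function(i) truth + stats::rnorm(80, sd = stats::runif(1, 0.1, 1)))
      list(P = P, truth = truth)
    })
    w <- optimize_weights(dat$P, dat$truth)
    single <- apply(dat$P, 2, function(p) mean((p - dat$truth)^2))
    expect_lte(attr(w, "mse"), min(single) + 1e-12)
    expect_equal(sum(as.numeric(w)), 1, tolerance = 1e-12)
    expect_true(all(as.numeric(w) >= 0))
  }
})

test_that("degenerate identical modules fall back to uniform weights", {
  y <- c(1, 2, 3, 4)
  expect_warning(
    w <- optimize_weights(cbind(y, y), y + 0.1),
    "identical"
  )
  expect_equal(as.numeric(w), c(0.5, 0.5))
  expect_equal(attr(w, "mse"), 0.01, tolerance = 1e-12)
})

test_that("prediction metrics match hand arithmetic", {
  exact <- prediction_metrics(c(1, 2, 3), c(1, 2, 3), epsilon = 0)
  expect_equal(exact$mse, 0)
  expect_equal(exact$accuracy, 1)

  m <- prediction_metrics(c(2, 4), c(0, 0), epsilon = 0.1)
  expect_equal(m$mse, 10)
  expect_equal(m$rmse, sqrt(10), tolerance = 1e-12)
  expect_equal(m$rmse^2, m$mse, tolerance = 1e-12)

  half <- prediction_metrics(c(0.05, 0.2), c(0, 0), epsilon = 0.1)
  expect_equal(half$accuracy, 0.5)
  expect_error(prediction_metrics(numeric(0), numeric(0)), "empty")
})

test_that("accuracy is monotone in its tolerance and saturates at 1", {
  err <- phytofuse:::with_seed(9, stats::rnorm(100))
  eps <- c(0, 0.1, 0.5, 1, 2, Inf)
  acc <- vapply(eps, function(e) prediction_metrics(err, rep(0, 100), e)$accuracy, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_equal(acc[length(acc)], 1)
})

test_that("restoration indicators follow their definitions", {
  expect_equal(delta_fertility(0.85, 0.70), 0.15)
  expect_equal(delta_fertility(0.5, 0.5), 0)
  af <- c(0.8, 0.9); bf <- c(0.6, 0.7)
  expect_equal(mean(delta_fertility(af, bf)), delta_fertility(mean(af), mean(bf)))

  expect_equal(pipgr(1.18, 1.00), 18)
  expect_equal(pipgr(1.22, 1.00), 22)
  expect_equal(pipgr(2, 2), 0)
  expect_error(pipgr(1.1, 0), "positive")
})

test_that("Shannon index matches closed forms and the vegan implementation", {
  expect_equal(shannon_index(c(10)), 0)
  expect_equal(shannon_index(c(5, 5, 5, 5)), log(4), tolerance = 1e-12)
  expect_equal(shannon_index(c(2, 1, 1)), -sum(c(0.5, 0.25, 0.25) * log(c(0.5, 0.25, 0.25))),
    tolerance = 1e-12
  )
  # zero counts are dropped; scale invariance
  expect_equal(shannon_index(c(3, 0, 1)), shannon_index(c(3, 1)))
  expect_equal(shannon_index(c(3, 1)), shannon_index(c(30, 10)), tolerance = 1e-12)
  counts <- phytofuse:::with_seed(11, stats::rpois(8, 20) + 1)
  expect_equal(shannon_index(counts), unname(vegan::diversity(counts, "shannon")),
    tolerance = 1e-12
  )
  expect_lte(shannon_index(counts), log(8) + 1e-12)
  expect_error(shannon_index(c(0, 0)), "zero")
})

test_that("evaluate_run fuses, ablates, and reports restoration indicators", {
  dat <- phytofuse:::with_seed(13, {
    truth_v <- stats::rnorm(40); truth_t <- stats::rnorm(40)
    mk <- function(tr, sd) tr + stats::rnorm(40, sd = sd)
    list(
      val = list(biogeochem = mk(truth_v, 0.1), dnn = mk(truth_v, 0.3)),
      test = list(biogeochem = mk(truth_t, 0.1), dnn = mk(truth_t, 0.3)),
      truth_v = truth_v, truth_t = truth_t
    )
  })
  solo <- evaluate_run(dat$val, dat$truth_v, dat$test, dat$truth_t,
    enabled = "biogeochem"
  )
  expect_equal(solo$fused_test, dat$test$biogeochem)
  expect_equal(as.numeric(solo$weights), 1)

  survey <- generate_restoration_survey(50, noise_sd = 0, seed = 2)
  full <- evaluate_run(dat$val, dat$truth_v, dat$test, dat$truth_t, survey = survey)
  expect_lte(
    mean((weighted_fusion(dat$val, full$weights) - dat$truth_v)^2),
    min(vapply(dat$val, function(p) mean((p - dat$truth_v)^2), numeric(1))) + 1e-12
  )
  expect_equal(full$restoration$delta_F, 0.15, tolerance = 1e-12)
  expect_equal(full$restoration$pipgr_percent, 18, tolerance = 1e-12)
  expect_gt(full$restoration$shannon_after, full$restoration$shannon_before)
  expect_error(evaluate_run(dat$val, dat$truth_v, dat$test, dat$truth_t,
    enabled = character(0)
  ), "no enabled")
})
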