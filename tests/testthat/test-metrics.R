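# Metric formulas against hand-computed values and vector-based oracles.

test_that("classification metrics match hand evaluation", {
  perfect <- classification_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(unname(unlist(perfect)), rep(1, 7))

  m <- classification_metrics(list(tp = 3, tn = 4, fp = 1, fn = 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$ner, 0.7)
  expect_equal(m$mcc, 10 / sqrt(600))

  expect_error(classification_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)),
               "zero")
})

test_that("NER is the mean of sensitivity and specificity", {
  # the benchmark comparison values: sens 0.88, spec 0.82 -> NER 0.85
  expect_equal((0.88 + 0.82) / 2, 0.85)
  m <- classification_metrics(list(tp = 88, fn = 12, tn = 82, fp = 18))
  expect_equal(m$sensitivity, 0.88)
  expect_equal(m$specificity, 0.82)
  expect_equal(m$ner, 0.85)
})

test_that("zero denominators give undefined markers, not NaN", {
  m <- classification_metrics(list(tp = 0, tn = 5, fp = 0, fn = 5))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$mcc))
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 0.5)
})

test_that("delta metrics are absolute differences", {
  expect_equal(delta_metric(0.85, 0.83), 0.02)
  expect_equal(delta_metric(0.83, 0.69), 0.14)
  expect_equal(delta_metric(0.5, 0.5), 0)
  expect_true(is.na(delta_metric(NA, 0.5)))
})

test_that("metric formulas agree with a vector-based oracle over all small
           confusion tables", {
  # independent route: rebuild label vectors from counts and use elementwise
  # means / Pearson correlation (which equals the MCC for binary vectors)
  for (total in c(4L, 9L, 15L)) {
    combos <- expand.grid(tp = 0:total, tn = 0:total, fp = 0:total)
    combos$fn <- total - combos$tp - combos$tn - combos$fp
    combos <- combos[combos$fn >= 0, ]
    for (r in seq_len(nrow(combos))) {
      cc <- as.list(combos[r, ])
      if (sum(unlist(cc)) == 0) next
      actual <- rep(c(1, 0, 0, 1), unlist(cc))
      pred <- rep(c(1, 0, 1, 0), unlist(cc))
      m <- classification_metrics(cc)
      expect_equal(m$accuracy, mean(actual == pred))
      if (!is.na(m$sensitivity))
        expect_equal(m$sensitivity, mean(pred[actual == 1]))
      if (!is.na(m$specificity))
        expect_equal(m$specificity, 1 - mean(pred[actual == 0]))
      if (!is.na(m$mcc))
        expect_equal(m$mcc, suppressWarnings(cor(actual, pred)),
                     tolerance = 1e-12)
      if (!is.na(m$precision) && !is.na(m$sensitivity) &&
          (m$precision + m$sensitivity) > 0)
        expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                       (m$precision + m$sensitivity))
    }
  }
})

test_that("metric symmetries hold", {
  set.seed(2)
  for (i in 1:25) {
    cc <- as.list(stats::rmultinom(1, 40, c(0.3, 0.3, 0.2, 0.2))[, 1])
    names(cc) <- c("tp", "tn", "fp", "fn")
    m <- classification_metrics(cc)
    # label-swap symmetry
    sw <- classification_metrics(list(tp = cc$tn, tn = cc$tp,
                                      fp = cc$fn, fn = cc$fp))
    expect_equal(m$accuracy, sw$accuracy)
    if (!is.na(m$mcc)) expect_equal(m$mcc, sw$mcc)
    if (!is.na(m$ner)) {
      expect_equal(m$ner, sw$ner)
      expect_equal(m$sensitivity, sw$specificity)
    }
    # F1 scale invariance
    sc <- classification_metrics(lapply(cc, function(v) 3L * v))
    if (!is.na(m$f1)) expect_equal(m$f1, sc$f1)
    if (!is.na(m$mcc)) expect_true(m$mcc >= -1 && m$mcc <= 1)
  }
})

test_that("regression metrics follow their definitions", {
  y <- c(1, 2, 3)
  m <- regression_metrics(y, c(1, 2, 4))
  expect_equal(m$r2, 0.5)
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$mse, 1 / 3)

  perfect <- regression_metrics(y, y)
  expect_equal(unclass(perfect), list(r2 = 1, mae = 0, mse = 0))
  expect_equal(regression_metrics(y, rep(mean(y), 3))$r2, 0)
  expect_warning(mc <- regression_metrics(c(2, 2, 2), c(1, 2, 3)),
                 "constant")
  expect_true(is.na(mc$r2))
  # Jensen: mae^2 <= mse
  set.seed(3)
  for (i in 1:10) {
    yy <- rnorm(20); pp <- rnorm(20)
    mm <- regression_metrics(yy, pp)
    expect_lte(mm$mae^2, mm$mse + 1e-12)
  }
})

test_that("confidence intervals use the t multiplier", {
  ci <- confidence_interval(c(0, 1))
  expect_equal(ci$mean, 0.5)
  expect_equal(ci$sd, sd(c(0, 1)))
  expect_equal(ci$margin, qt(0.975, 1) * sd(c(0, 1)) / sqrt(2))
  expect_equal(ci$lower, ci$mean - ci$margin)

  expect_equal(confidence_interval(rep(0.8, 5))$margin, 0)
  expect_error(confidence_interval(1), "at least 2")

  # oracle recomputation on 19 synthetic draws
  set.seed(19)
  v <- rnorm(19, 0.9, 0.01)
  ci19 <- confidence_interval(v)
  expect_equal(ci19$margin,
               qt(0.975, 18) * sd(v) / sqrt(19), tolerance = 1e-9)
  # t.test as an independent check of the interval
  tt <- t.test(v)
  expect_equal(unname(tt$conf.int[1]), ci19$lower, tolerance = 1e-9)
  expect_warning(confidence_interval(c(0.5, 0.7, NA)), "undefined")
})

test_that("Bland-Altman statistics and agreement classification", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_lower, 0)
  expect_equal(ba0$loa_upper, 0)

  d <- c(0.01, 0.03, 0.02)
  ba <- bland_altman(d + 1, rep(1, 3))
  expect_equal(ba$bias, 0.02)
  expect_equal(ba$sd_diff, 0.01)
  expect_equal(ba$loa_lower, 0.0004)
  expect_equal(ba$loa_upper, 0.0396)
  expect_true(within_agreement(ba, 0.03))
  expect_false(within_agreement(ba, 0.5))
  expect_true(ba$loa_lower <= ba$bias && ba$bias <= ba$loa_upper)

  expect_error(bland_altman(c(1, 2), c(1, 2)), "3 pairs")
})
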