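test_that("error summary implements the RMSE and sample-SD formulas", {
  s <- measure_series(c(1, 2, 3), c(1, 2, 3))
  es <- error_summary(s)
  expect_equal(es$rmse, 0)
  expect_equal(es$sd, 0)
  es2 <- error_summary(measure_series(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(es2$rmse, 3)
  expect_equal(es2$sd, 0)
  V <- c(1, -1, 2)
  es3 <- error_summary(measure_series(V, c(0, 0, 0)))
  expect_equal(es3$rmse, sqrt(2))
  expect_equal(es3$sd, sqrt(sum((V - mean(V))^2) / 2))
  expect_error(measure_series(1:3, 1:4), "length")
  # identity RMSE^2 = Vbar^2 + (n-1)/n * SD^2
  set.seed(2)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    v <- rnorm(n); w <- rnorm(n)
    es <- error_summary(measure_series(v, w))
    expect_equal(es$rmse^2, es$v_bar^2 + (n - 1) / n * es$sd^2,
                 tolerance = 1e-12)
  }
})

test_that("ICC(2,1) equals the ANOVA mean-squares oracle", {
  # 6-subject toy table
  method <- c(10.1, 12.4, 9.8, 15.2, 11.0, 13.3)
  manual <- c(10.6, 11.9, 10.3, 14.1, 11.8, 12.9)
  ic <- icc_absolute(measure_series(method, manual))
  # oracle: stats::aov mean squares + Shrout-Fleiss ICC(A,1)
  df <- data.frame(y = c(method, manual),
                   subj = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  oracle <- (msr - mse) / (msr + mse + 2 / 6 * (msc - mse))
  expect_equal(ic$icc, oracle, tolerance = 1e-10)
  # lme4 variance-components route agrees on balanced data
  fit <- suppressMessages(lme4::lmer(y ~ 1 + (1 | subj) + (1 | rater),
                                     data = df))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vs <- vc$vcov[vc$grp == "subj"]
  vr <- vc$vcov[vc$grp == "rater"]
  ve <- vc$vcov[vc$grp == "Residual"]
  # REML components differ from the moment estimators at the margin
  expect_equal(ic$icc, vs / (vs + vr + ve), tolerance = 5e-3)
})

test_that("ICC bands, bias penalty and degenerate cases behave", {
  v <- c(1, 5, 9, 13, 2, 7)
  ic <- icc_absolute(measure_series(v, v))
  expect_equal(ic$icc, 1)
  expect_equal(ic$band, "excellent")
  # constant offset: absolute agreement < 1, consistency would be 1
  ic2 <- icc_absolute(measure_series(v + 10, v))
  expect_lt(ic2$icc, 1)
  expect_equal(stats::cor(v + 10, v), 1)
  # rater exchange invariance
  set.seed(3)
  a <- rnorm(10); b <- a + rnorm(10, 0, 0.3)
  expect_equal(icc_absolute(measure_series(a, b))$icc,
               icc_absolute(measure_series(b, a))$icc, tolerance = 1e-12)
  icz <- icc_absolute(measure_series(rep(2, 5), rep(2, 5)))
  expect_true(is.na(icz$icc))
  expect_equal(icz$band, "undefined")
  expect_error(icc_absolute(measure_series(1:2, 2:3)), "n >= 3")
})

test_that("Bland-Altman limits and CIs follow the classic formulas", {
  s <- measure_series(c(3, 4, 5), c(3, 4, 5))
  ba <- bland_altman(s)
  expect_equal(ba$mean_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))
  ba2 <- bland_altman(measure_series(c(-2, 0, 2), c(0, 0, 0)))
  expect_equal(ba2$mean_diff, 0)
  expect_equal(ba2$sd_diff, 2)
  expect_equal(c(ba2$loa_low, ba2$loa_high), c(-3.92, 3.92))
  tq <- qt(0.975, 2)
  expect_equal(ba2$ci_mean, c(-1, 1) * tq * 2 / sqrt(3))
  expect_equal(ba2$ci_loa_high, 3.92 + c(-1, 1) * tq * 2 * sqrt(3 / 3))
  expect_error(bland_altman(measure_series(1:2, 2:1)), "n >= 3")
})

test_that("the limits of agreement cover ~95% of Gaussian differences", {
  set.seed(11)
  d <- rnorm(4000, 1, 2)
  ba <- bland_altman(measure_series(d, rep(0, 4000)))
  cover <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_equal(cover, 0.95, tolerance = 0.015)
})

test_that("ROC analysis matches the concordance oracle and pROC", {
  set.seed(4)
  scores <- rnorm(20)
  labels <- rbinom(20, 1, 0.5)
  if (length(unique(labels)) == 1) labels[1] <- 1 - labels[1]
  r <- roc_analysis(scores, labels, direction = "high")
  # O(n^2) Mann-Whitney concordance with ties counted 1/2
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  conc <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(r$auc, conc, tolerance = 1e-12)
  pr <- suppressMessages(pROC::roc(labels, scores, direction = "<",
                                   quiet = TRUE))
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  # invariance under strictly monotone transforms
  r2 <- roc_analysis(exp(scores), labels, direction = "high")
  expect_equal(r2$auc, r$auc, tolerance = 1e-12)
})

test_that("Youden cut, orientation and degenerate ROC inputs behave", {
  # perfect separation
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  expect_equal(r$sens_at_cut, 1)
  expect_equal(r$spec_at_cut, 1)
  # uninformative test
  r2 <- roc_analysis(rep(5, 8), rep(c(0, 1), 4))
  expect_equal(r2$auc, 0.5)
  expect_equal(r2$youden_j, 0)
  # disease flagged by LOW scores: auto-orientation keeps AUC >= 0.5
  set.seed(6)
  len_healthy <- rnorm(15, 2400, 300)
  len_disease <- rnorm(15, 1700, 300)
  r3 <- roc_analysis(c(len_healthy, len_disease), rep(c(0, 1), each = 15))
  expect_gte(r3$auc, 0.5)
  expect_equal(r3$direction, "low")
  # forcing the wrong direction mirrors the AUC
  r4 <- roc_analysis(c(len_healthy, len_disease), rep(c(0, 1), each = 15),
                     direction = "high")
  expect_equal(r4$auc, 1 - r3$auc, tolerance = 1e-12)
  expect_error(roc_analysis(1:5, rep(1, 5)), "class")
})
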