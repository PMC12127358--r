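test_that("model fitting recovers generator truth and enforces per-state minimums", {
  cfg <- synthetic_config(
    n = 4000, prior_pos = 0.5,
    sedep = list(mu_pos = 70, s_pos = 10, mu_neg = 50, s_neg = 10,
                 criterion = 60),
    decision_noise = 0, seed = 77)
  sim <- simulate_cohort(cfg)
  fit <- uvsdt(sim$cohort, "sedep")
  cf <- coef(fit)
  expect_lt(abs(cf[["mu_pos"]] - 70), 1)
  expect_lt(abs(cf[["s_pos"]] - 10), 1)
  expect_lt(abs(cf[["mu_neg"]] - 50), 1)
  expect_lt(abs(cf[["s_neg"]] - 10), 1)
  expect_equal(fit$prior_pos, fit$n_pos / (fit$n_pos + fit$n_neg))

  # balanced truth states give a balanced prior
  expect_lt(abs(fit$prior_pos - 0.5), 0.05)

  # too few positive-state records: error names the state
  df <- tiny_cohort_df()
  df <- do.call(rbind, replicate(4, df, simplify = FALSE))
  df$id <- sprintf("r%02d", seq_len(nrow(df)))
  df$thi_post <- df$thi_baseline - 2   # nobody improves > 7
  df$thi_post[1:3] <- df$thi_baseline[1:3] - 20  # exactly 3 T_pos
  expect_error(uvsdt(cohort(df), "sedep"), "T_pos")
})

test_that("double-logit ROC parameters follow the closed form exactly", {
  m <- uvsdt_model(logis_dist(70, 10), logis_dist(50, 10))
  acc <- roc_accuracy(m)
  expect_equal(acc$roc_slope, 1)
  expect_equal(acc$roc_intercept, 2)

  # identical truth-state distributions: chance performance
  m0 <- uvsdt_model(logis_dist(60, 10), logis_dist(60, 10))
  acc0 <- roc_accuracy(m0)
  expect_equal(acc0$roc_slope, 1)
  expect_equal(acc0$roc_intercept, 0)
  expect_equal(acc0$curve$logit_tp, acc0$curve$logit_fp)

  # unequal variances
  m2 <- uvsdt_model(logis_dist(70, 20), logis_dist(50, 10))
  acc2 <- roc_accuracy(m2)
  expect_equal(acc2$roc_slope, 0.5)
  expect_equal(acc2$roc_intercept, 1)

  # exact affinity of (logit FP, logit TP) for arbitrary models
  set.seed(19)
  for (i in 1:25) {
    m <- random_model()
    a <- roc_accuracy(m, grid = seq(10, 90, length.out = 101))
    dev <- a$curve$logit_tp - (a$roc_slope * a$curve$logit_fp + a$roc_intercept)
    expect_lt(max(abs(dev)), 1e-9)
  }
})

test_that("likelihood-ratio curves respect identity, symmetry and prior-odds modes", {
  m0 <- uvsdt_model(logis_dist(60, 10), logis_dist(60, 10))
  lr0 <- likelihood_ratio(m0)
  expect_true(all(abs(lr0$lr[!lr0$flagged] - 1) < 1e-12))

  m <- uvsdt_model(logis_dist(70, 10), logis_dist(50, 10))
  expect_equal(likelihood_ratio(m, grid = 60)$lr, 1)

  # posterior-odds mode multiplies by the prior odds
  m3 <- uvsdt_model(logis_dist(70, 10), logis_dist(50, 10), prior_pos = 0.25)
  g <- seq(20, 100, length.out = 41)
  dens <- likelihood_ratio(m3, g, mode = "density_ratio")
  post <- likelihood_ratio(m3, g, mode = "posterior_odds")
  expect_equal(post$lr, dens$lr * (0.25 / 0.75))

  # equal scales, mu_pos > mu_neg: strictly increasing in the driver
  expect_true(all(diff(dens$lr) > 0))

  # far-tail underflow points are flagged, not propagated
  mfar <- uvsdt_model(logis_dist(100, 5), logis_dist(5, 0.15))
  lrf <- likelihood_ratio(mfar, grid = seq(0, 130, length.out = 512))
  expect_true(any(lrf$flagged))
  expect_true(all(is.na(lrf$lr[lrf$flagged])))
  expect_true(all(is.finite(lrf$lr[!lrf$flagged])))
})

test_that("unbiased criterion is the likelihood-ratio unit crossing", {
  m <- uvsdt_model(logis_dist(70, 10), logis_dist(50, 10))
  ub <- unbiased_criterion(m)
  expect_equal(ub, 60, tolerance = 1e-9)
  expect_lt(abs(likelihood_ratio(m, ub)$lr - 1), 1e-6)

  # unequal scales: verify every root against a dense grid-scan oracle
  m2 <- uvsdt_model(logis_dist(70, 15), logis_dist(50, 10))
  ub2 <- suppressWarnings(unbiased_criterion(m2))
  grid <- seq(0, 130, by = 0.001)
  lr <- likelihood_ratio(m2, grid)$lr - 1
  sign_flip <- which(sign(lr[-1]) * sign(lr[-length(lr)]) < 0)
  expect_equal(length(ub2), length(sign_flip))
  for (k in seq_along(sign_flip))
    expect_lt(abs(ub2[k] - grid[sign_flip[k]]), 0.002)
  for (r in ub2) expect_lt(abs(likelihood_ratio(m2, r)$lr - 1), 1e-6)

  # identical distributions: no isolated root
  m0 <- uvsdt_model(logis_dist(60, 10), logis_dist(60, 10))
  expect_error(unbiased_criterion(m0), "no unbiased criterion")
})

test_that("optimal criterion matches the prior-odds/payoff target ratio", {
  m <- uvsdt_model(logis_dist(70, 10), logis_dist(50, 10))
  # equal priors and payoffs: beta = 1, optimal = unbiased
  oc <- optimal_criterion(m, payoff_matrix())
  expect_equal(oc$beta, 1)
  expect_lt(abs(oc$criterion - unbiased_criterion(m)), 1e-6)

  # prior odds 2, equal payoffs: beta = 2 and L(c) = 2
  m2 <- uvsdt_model(logis_dist(70, 10), logis_dist(50, 10), prior_pos = 1 / 3)
  oc2 <- optimal_criterion(m2, payoff_matrix())
  expect_equal(oc2$beta, 2)
  expect_lt(abs(likelihood_ratio(m2, oc2$criterion)$lr - 2), 1e-6)

  # payoff ratio 7 with equal priors: beta = 7
  oc7 <- optimal_criterion(m, payoff_matrix(benefit_pos = 0.5, cost_miss = 0.5,
                                            benefit_neg = 3.5, cost_fa = 3.5))
  expect_equal(oc7$beta, 7)

  # unattainable target reports the attainable range
  mflat <- uvsdt_model(logis_dist(61, 10), logis_dist(60, 10))
  expect_error(
    optimal_criterion(mflat, payoff_matrix(benefit_neg = 1e6)),
    "unattainable")

  expect_error(payoff_matrix(benefit_pos = -1), "non-negative")
})

test_that("criterion classification uses the unit band", {
  expect_equal(classify_criterion(2), "strict")
  expect_equal(classify_criterion(0.5), "lenient")
  expect_equal(classify_criterion(1), "unbiased")
  expect_equal(classify_criterion(c(1.04, 1.06, 0.96, 0.94)),
               c("unbiased", "strict", "unbiased", "lenient"))
  expect_equal(classify_criterion(1.2, tol = 0.3), "unbiased")
  expect_error(classify_criterion(-1), "> 0")
})

test_that("model methods (predict, simulate, summary, logLik) are coherent", {
  sim <- simulate_cohort(recovery_config(600, seed = 3))
  fit <- uvsdt(sim$cohort, "sedep")

  g <- seq(10, 120, length.out = 25)
  lr <- predict(fit, g, type = "lr")
  post <- predict(fit, g, type = "posterior")
  # posterior odds = prior odds * density ratio
  expect_equal(post / (1 - post),
               lr * fit$prior_pos / fit$prior_neg, tolerance = 1e-9)
  expect_equal(predict(fit, g, type = "tp"),
               1 - logistic_cdf(fit$dist_pos, g))

  dr <- simulate(fit, nsim = 5000, seed = 4)
  expect_equal(nrow(dr), 5000)
  expect_lt(abs(mean(dr$truth == "T_pos") - fit$prior_pos), 0.03)
  expect_lt(abs(stats::median(dr$driver[dr$truth == "T_pos"]) - fit$dist_pos$mu),
            1)

  s <- summary(fit)
  expect_s3_class(s, "summary.uvsdt")
  expect_equal(s$roc_slope, coef(fit)[["roc_slope"]])
  expect_true(is.finite(as.numeric(logLik(fit))))
})
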