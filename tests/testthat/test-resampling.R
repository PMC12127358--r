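test_that("leave-one-out datasets enumerate single deletions exhaustively", {
  sim <- simulate_cohort(synthetic_config(n = 20, seed = 2))
  loo <- make_loo_datasets(sim$cohort)
  expect_length(loo, 20)
  expect_true(all(vapply(loo, nrow, integer(1)) == 19L))
  absent <- vapply(seq_along(loo),
                   function(i) setdiff(sim$cohort$id, loo[[i]]$id),
                   character(1))
  expect_setequal(absent, sim$cohort$id)       # each id absent exactly once
  expect_equal(absent, sort(sim$cohort$id))    # deterministic order by id
  expect_equal(names(loo), absent)

  # smallest admissible cohort
  sim6 <- simulate_cohort(synthetic_config(n = 6, seed = 2))
  expect_length(make_loo_datasets(sim6$cohort), 6)
  sim5 <- simulate_cohort(synthetic_config(n = 5, seed = 2))
  expect_error(make_loo_datasets(sim5$cohort), "at least 6")
})

test_that("random partitions are exact complements and reproducible", {
  sim <- simulate_cohort(synthetic_config(seed = 4))   # n = 143
  parts <- make_random_partitions(sim$cohort, partition_size = 72,
                                  n_reps = 100, seed = 9)
  expect_length(parts$partition1, 100)
  expect_length(parts$partition2, 100)
  expect_true(all(vapply(parts$partition1, nrow, integer(1)) == 72L))
  expect_true(all(vapply(parts$partition2, nrow, integer(1)) == 71L))
  for (r in c(1, 50, 100)) {
    ids1 <- parts$partition1[[r]]$id
    ids2 <- parts$partition2[[r]]$id
    expect_length(intersect(ids1, ids2), 0)
    expect_setequal(c(ids1, ids2), sim$cohort$id)
  }
  again <- make_random_partitions(sim$cohort, 72, 100, seed = 9)
  expect_identical(lapply(parts$partition1, `[[`, "id"),
                   lapply(again$partition1, `[[`, "id"))
  other <- make_random_partitions(sim$cohort, 72, 5, seed = 10)
  expect_false(identical(parts$partition1[[1]]$id, other$partition1[[1]]$id))
  expect_error(make_random_partitions(sim$cohort, 143), "smaller")
})

test_that("per-dataset refits succeed on healthy cohorts and log skipped fits", {
  sim <- simulate_cohort(synthetic_config(n = 60, seed = 8))
  loo <- make_loo_datasets(sim$cohort)
  est <- fit_all(loo, "sedep")
  expect_equal(nrow(est$params), 60)
  expect_length(est$failures, 0)
  expect_equal(dim(est$lr), c(60, length(est$grid)))

  # single-deletion stability: the spread over LOO refits is bounded by the
  # most extreme single-deletion refit (oracle: direct re-fit after deleting
  # the records with extreme drivers)
  full <- coef(uvsdt(sim$cohort, "sedep"))[["roc_slope"]]
  expect_lt(max(est$params$roc_slope) - min(est$params$roc_slope),
            2 * max(abs(est$params$roc_slope - full)) + 1e-12)

  # datasets below 5 records in a state are skipped with a reason
  df <- as.data.frame(sim$cohort)
  lab <- label_truth_state(df)
  keep <- c(which(lab == "T_pos")[1:5], which(lab == "T_neg"))
  small <- cohort(df[keep, ])
  loo2 <- make_loo_datasets(small)
  est2 <- fit_all(loo2, "sedep")
  expect_gt(length(est2$failures), 0)
  expect_match(unlist(est2$failures)[1], "T_pos")
  expect_equal(nrow(est2$params) + length(est2$failures), nrow(small))

  # all datasets failing is an error
  tiny <- cohort(df[c(which(lab == "T_pos")[1:5], which(lab == "T_neg")[1:2]), ])
  expect_error(fit_all(make_loo_datasets(tiny), "sedep"), "all datasets failed")
})

test_that("IQR fence outlier rule matches hand-computed retention", {
  r <- remove_outliers(c(1, 2, 3, 4, 5))
  expect_equal(r$retained, c(1, 2, 3, 4, 5))
  expect_equal(r$n_removed, 0L)

  # type-7 quartiles of [1,2,3,4,1000]: Q1 = 2, Q3 = 4, fences [-1, 7]
  r2 <- remove_outliers(c(1, 2, 3, 4, 1000))
  expect_equal(r2$retained, c(1, 2, 3, 4))
  expect_equal(r2$n_removed, 1L)

  r3 <- remove_outliers(rep(7, 10))
  expect_equal(r3$n_removed, 0L)

  expect_warning(r4 <- remove_outliers(c(1, 2, 1000)), "fewer than 4")
  expect_equal(r4$n_removed, 0L)

  # NAs are dropped, not treated as outliers
  r5 <- remove_outliers(c(1, 2, 3, 4, NA, 1000))
  expect_equal(r5$n_removed, 1L)
  expect_equal(r5$retained, c(1, 2, 3, 4))
})

test_that("percentile summaries match analytic quantiles and are permutation-invariant", {
  # degenerate: identical estimates collapse the band
  sim <- simulate_cohort(synthetic_config(n = 40, seed = 21))
  est <- fit_all(make_loo_datasets(sim$cohort)[1:6], "sedep")
  est$params$roc_slope <- rep(1.5, 6)
  s <- summarize_estimates(est)
  row <- s$params[s$params$parameter == "roc_slope", ]
  expect_equal(c(row$median, row$p2.5, row$p97.5), rep(1.5, 3))

  # analytic quantile oracle on a known normal
  set.seed(90)
  v <- stats::rnorm(1000, mean = 10, sd = 2)
  ps <- uvsdt:::pct_summary(v)
  expect_lt(abs(ps[["median"]] - 10) / 10, 0.03)
  # fence screening trims a fraction of both tails, so compare against the
  # analytic quantiles of the screened distribution only loosely
  expect_lt(abs(ps[["p2.5"]] - stats::qnorm(0.025, 10, 2)) /
              abs(stats::qnorm(0.025, 10, 2)), 0.05)
  expect_lt(abs(ps[["p97.5"]] - stats::qnorm(0.975, 10, 2)) /
              stats::qnorm(0.975, 10, 2), 0.05)
  expect_true(ps[["p2.5"]] <= ps[["median"]] &&
                ps[["median"]] <= ps[["p97.5"]])

  # permutation invariance in dataset order
  est2 <- est
  perm <- c(4, 1, 6, 2, 5, 3)
  est2$params <- est2$params[perm, ]
  est2$lr <- est2$lr[perm, ]
  s2 <- summarize_estimates(est2)
  expect_equal(s2$params, s$params)
  expect_equal(s2$lr_band, s$lr_band)
})

test_that("percentile-interval tests reject exactly when the null is outside", {
  # direct re-implementation as the oracle on randomized summaries
  set.seed(55)
  for (i in 1:50) {
    lo <- stats::runif(1, -2, 2); hi <- lo + stats::runif(1, 0, 3)
    param <- sample(c("roc_intercept", "roc_slope"), 1)
    null <- if (param == "roc_intercept") 0 else 1
    res <- test_vs_null(list(p2.5 = lo, p97.5 = hi), param)
    expect_equal(res$reject, null < lo || null > hi)
    expect_equal(res$null_value, null)
  }

  # between-group disjointness rule
  expect_true(compare_groups(list(p2.5 = -1.277, p97.5 = -0.857),
                             list(p2.5 = 0.888, p97.5 = 6.005),
                             "roc_intercept")$reject)
  expect_false(compare_groups(list(p2.5 = 0.3, p97.5 = 1.1),
                              list(p2.5 = 0.3, p97.5 = 1.1),
                              "roc_slope")$reject)
  expect_false(compare_groups(list(p2.5 = 0.363, p97.5 = 1.098),
                              list(p2.5 = 0.916, p97.5 = 4.091),
                              "roc_slope")$reject)
})

test_that("ROC and likelihood-ratio bands summarise resampled curves pointwise", {
  sim <- simulate_cohort(recovery_config(400, seed = 14))
  loo <- make_loo_datasets(sim$cohort)
  est <- fit_all(loo, "sedep")

  band <- empirical_roc_band(est)
  expect_equal(band$criterion, est$grid)
  expect_true(all(band$logit_tp_lo <= band$logit_tp_median + 1e-12))
  expect_true(all(band$logit_tp_hi >= band$logit_tp_median - 1e-12))

  # single dataset: the band collapses onto the curve
  est1 <- fit_all(loo[1], "sedep")
  b1 <- empirical_roc_band(est1)
  expect_equal(b1$logit_tp_lo, b1$logit_tp_hi)
  expect_equal(b1$logit_tp_lo, b1$logit_tp_median)

  # median LR crosses 1 near the truth-state midpoint (truth 65 here)
  lb <- lr_band(est)
  ok <- !lb$masked & !is.na(lb$median)
  cross <- lb$grid[ok][which.min(abs(log(lb$median[ok])))]
  step <- diff(est$grid[1:2])
  expect_lt(abs(cross - 65), 3 + 2 * step)

  # identical-state truth: median curve sits on the diagonal, LR band at 1.
  # Relabel at random (independently of the hearing driver) so both truth
  # states share one driver distribution.
  df <- as.data.frame(sim$cohort)
  set.seed(31)
  improve <- stats::runif(nrow(df)) < 0.5 & df$thi_baseline >= 20
  df$thi_post <- df$thi_baseline - ifelse(improve, 20, 0)
  est0 <- fit_all(make_loo_datasets(cohort(df))[1:25], "sedep")
  b0 <- summarize_estimates(est0)
  okk <- !b0$lr_band$masked & !is.na(b0$lr_band$median)
  mid <- abs(b0$lr_band$grid - 65) < 20
  expect_lt(max(abs(log(b0$lr_band$median[okk & mid]))), 0.5)
})

test_that("bootstrap resampling provides a sampling-variance companion band", {
  sim <- simulate_cohort(recovery_config(300, seed = 17))
  est <- bootstrap_estimates(sim$cohort, "sedep", n_reps = 30, seed = 5)
  expect_equal(nrow(est$params), 30)
  s <- summarize_estimates(est)
  # bootstrap intervals are much wider than LOO deletion-sensitivity bands
  loo <- summarize_estimates(fit_all(make_loo_datasets(sim$cohort), "sedep"))
  w_boot <- diff(unlist(s$params[s$params$parameter == "roc_slope",
                                 c("p2.5", "p97.5")]))
  w_loo <- diff(unlist(loo$params[loo$params$parameter == "roc_slope",
                                  c("p2.5", "p97.5")]))
  expect_gt(w_boot, w_loo)
})
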