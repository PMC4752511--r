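make_trials <- function(pro = numeric(0), anti_correct = numeric(0),
                        anti_error = numeric(0)) {
  rbind(
    if (length(pro)) data.frame(trial_type = "pro", response = "correct",
                                rt_seconds = pro),
    if (length(anti_correct)) data.frame(trial_type = "anti",
                                         response = "correct",
                                         rt_seconds = anti_correct),
    if (length(anti_error)) data.frame(trial_type = "anti",
                                       response = "error",
                                       rt_seconds = anti_error))
}

test_that("summary statistics compute per-cell means, SDs and accuracy", {
  tr <- make_trials(pro = c(0.30, 0.35, 0.40),
                    anti_correct = c(0.5, 0.6, 0.7), anti_error = 0.25)
  s <- summary_stats(tr)
  expect_equal(s$pro_rt_mean, 0.35)
  expect_equal(s$pro_rt_sd, 0.05)
  expect_equal(s$anti_accuracy, 0.75)
  expect_equal(s$n_anti, 4)
  # empty error cell is missing, not zero
  s2 <- summary_stats(make_trials(pro = c(0.3, 0.4),
                                  anti_correct = c(0.5, 0.6)))
  expect_true(is.na(s2$anti_error_rt_mean))
  expect_equal(s2$anti_accuracy, 1)
  expect_error(summary_stats(make_trials(pro = c(0.3, 0.4))), "accuracy")
})

test_that("summary statistics match an independent recomputation", {
  p <- control_params()
  tr <- simulate_trials(p, 25, 25, seed = 21)
  s <- summary_stats(tr)
  # brute-force recomputation with subset/mean/sd directly
  pro <- subset(tr, trial_type == "pro")$rt_seconds
  ac <- subset(tr, trial_type == "anti" & response == "correct")$rt_seconds
  expect_equal(s$pro_rt_mean, sum(pro) / length(pro))
  expect_equal(s$pro_rt_sd, sqrt(sum((pro - mean(pro))^2) / (length(pro) - 1)))
  expect_equal(s$anti_correct_rt_mean, sum(ac) / length(ac))
  expect_equal(s$anti_accuracy, length(ac) / 25)
})

test_that("quantile-range means follow the (i - 0.5)/n assignment rule", {
  m <- quantile_range_means(1:10)
  expect_equal(m[1], 1)    # position 0.05 alone in 0-10%
  expect_equal(m[6], 10)   # position 0.95 alone in 90-100%
  expect_equal(m[2], mean(c(2, 3)))  # positions 0.15, 0.25
  # constant RTs: every non-empty range equals the constant
  mc <- quantile_range_means(rep(0.4, 12))
  expect_true(all(mc[!is.na(mc)] == 0.4))
  expect_error(quantile_range_means(numeric(0)), "no RTs")
})

test_that("quantile-range means match a brute-force assignment oracle", {
  set.seed(37)
  rts <- runif(37, 0.2, 0.8)
  got <- quantile_range_means(rts)
  # independent reimplementation: loop over sorted values and ranges
  x <- sort(rts)
  n <- length(x)
  rng <- delta_ranges()
  want <- numeric(6)
  for (r in 1:6) {
    vals <- c()
    for (i in 1:n) {
      pos <- (i - 0.5) / n
      hit <- if (r == 6) pos >= rng[r, 1] else pos >= rng[r, 1] && pos < rng[r, 2]
      if (hit) vals <- c(vals, x[i])
    }
    want[r] <- mean(vals)
  }
  expect_equal(got, want)
  # permutation invariance
  expect_equal(quantile_range_means(sample(rts)), got)
  # monotone across ranges
  expect_true(all(diff(got[!is.na(got)]) >= 0))
})

test_that("delta plot is zero for identical conditions and tracks shifts", {
  rts <- seq(0.3, 0.6, length.out = 20)
  tr0 <- make_trials(pro = rts, anti_correct = rts)
  d0 <- delta_plot(tr0)
  expect_equal(d0$y, rep(0, 6))
  shift <- make_trials(pro = rts, anti_correct = rts + 0.05)
  d1 <- delta_plot(shift)
  expect_equal(d1$y, rep(0.05, 6))
  expect_equal(d1$x, quantile_range_means(rts) + 0.025)
  # invariance to a common additive constant on all RTs
  tr2 <- make_trials(pro = rts + 0.2, anti_correct = rts + 0.25)
  expect_equal(delta_plot(tr2)$y, d1$y)
  # too few trials -> missing points, not an error
  expect_true(all(is.na(delta_plot(make_trials(pro = rts,
                                               anti_correct = 0.4))$y)))
})

test_that("model-simulated data show the decreasing delta-plot profile", {
  tr <- simulate_trials(control_params(), 2000, 2000, seed = 23)
  d <- delta_plot(tr)
  expect_gt(d$y[1], d$y[6])
  expect_true(all(diff(d$x) > 0))
})

test_that("group-averaged delta plot pools subjects with complete points", {
  spec <- test_cohort_spec(n_per_stage = c(4, 0, 0, 0, 0))
  coh <- generate_cohort(spec, seed = 3)
  g <- group_delta_plot(coh$trials)
  expect_equal(nrow(g), 6)
  expect_true(all(g$n_subjects <= 4))
  expect_true(all(is.finite(g$se)))
})

test_that("two-sample comparison matches the textbook pooled formula", {
  expect_equal(group_compare(c(1, 2, 3), c(1, 2, 3)),
               list(statistic = 0, df = 4, p_value = 1, degenerate = FALSE),
               tolerance = 1e-12)
  g <- group_compare(c(1, 2, 3), c(11, 12, 13))
  expect_lt(g$p_value, 0.001)
  set.seed(31)
  x <- rnorm(40); y <- rnorm(35, 0.4)
  got <- group_compare(x, y)
  sp <- sqrt(((39) * var(x) + (34) * var(y)) / (40 + 35 - 2))
  t_hand <- (mean(x) - mean(y)) / (sp * sqrt(1 / 40 + 1 / 35))
  expect_equal(got$statistic, t_hand, tolerance = 1e-10)
  expect_equal(got$df, 73)
  expect_equal(got$p_value, 2 * pt(-abs(t_hand), 73), tolerance = 1e-10)
  # degenerate variance flagged, not crashed
  dg <- group_compare(c(1, 1), c(2, 2))
  expect_true(dg$degenerate)
})
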