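test_that("bound transforms are inverse to each other and stay in the box", {
  lo <- c(0.1, 0.3); hi <- c(40, 5)
  x <- c(7.3, 1.4)
  th <- waldrace:::to_unconstrained(x, lo, hi)
  expect_equal(waldrace:::to_bounded(th, lo, hi), x, tolerance = 1e-8)
  expect_true(all(waldrace:::to_bounded(c(-50, 50), lo, hi) >= lo))
  expect_true(all(waldrace:::to_bounded(c(-50, 50), lo, hi) <= hi))
})

test_that("refitting with the same configuration is bitwise reproducible", {
  tr <- simulate_trials(control_params(), 60, 60, seed = 61)
  cfg <- fit_config(n_sims = 800, n_hops = 1, maxit = 120, restarts = 1,
                    seed = 3)
  f1 <- fit_subject(tr, cfg)
  f2 <- fit_subject(tr, cfg)
  expect_identical(f1$params_hat, f2$params_hat)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("fits respect bounds, flag low data and reject empty subjects", {
  tr <- simulate_trials(control_params(), 25, 12, seed = 62)
  cfg <- fit_config(n_sims = 500, n_hops = 1, maxit = 80, restarts = 1,
                    seed = 4)
  expect_warning(f <- fit_subject(tr, cfg), "fewer than 20")
  expect_true(f$low_data)
  b <- cfg$bounds
  p <- f$params_hat
  expect_true(p$v_pre >= b$v_pre[1] && p$v_pre <= b$v_pre[2])
  expect_true(p$v_exec >= b$v_exec[1] && p$v_exec <= b$v_exec[2])
  expect_true(p$t >= b$t[1] && p$t <= b$t[2])
  expect_true(p$t_exec >= b$t_exec[1] && p$t_exec <= b$t_exec[2])
  expect_true(is.finite(f$loglik))
  expect_error(fit_subject(tr[0, ], cfg), "no trials")
})

test_that("the fitted point dominates the generating parameters", {
  p <- control_params()
  tr <- simulate_trials(p, 500, 500, seed = 63)
  cfg <- test_fit_config(seed = 5)
  f <- fit_subject(tr, cfg)
  ll_truth <- total_loglik(p, tr, n_sims = cfg$n_sims, seed = cfg$seed)
  expect_gte(f$loglik, ll_truth - 1.0)
  # and the key drift is recovered to within a quarter of its value
  expect_lt(abs(f$params_hat$v_exec - p$v_exec) / p$v_exec, 0.25)
})

test_that("recovery report has one row per subject and parameter", {
  cfg <- fit_config(n_sims = 500, n_hops = 1, maxit = 60, restarts = 1,
                    seed = 6)
  rep <- suppressWarnings(
    recover_parameters(n_subjects = 3, n_pro = 30, n_anti = 30,
                       config = cfg, seed = 64))
  expect_equal(nrow(rep$table), 3 * 7)
  expect_equal(unique(table(rep$table$subject)), 7)
  expect_true(all(rep$summary$cor >= -1 & rep$summary$cor <= 1, na.rm = TRUE))
})

test_that("zero-variance truths give undefined, not crashing, correlations", {
  rng <- default_recovery_ranges()
  fixed <- lapply(rng, function(r) rep(mean(r), 2))
  cfg <- fit_config(n_sims = 500, n_hops = 1, maxit = 60, restarts = 1,
                    seed = 7)
  rep <- suppressWarnings(
    recover_parameters(n_subjects = 5, n_pro = 30, n_anti = 30,
                       ranges = fixed, config = cfg, seed = 65))
  expect_true(all(is.na(rep$summary$cor)))
  expect_true(all(is.finite(rep$summary$bias)))
})

test_that("AIC table follows 2k - 2 loglik and ranks variants", {
  tr <- simulate_trials(control_params(), 60, 60, seed = 66)
  cfg <- fit_config(n_sims = 800, n_hops = 1, maxit = 100, restarts = 1,
                    seed = 8)
  tab <- compare_models(tr, variants = list(
    shared_threshold = list(a_diff_free = FALSE),
    split_threshold = list(a_diff_free = TRUE)), config = cfg)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$aic, 2 * tab$k - 2 * tab$loglik)
  expect_true(all(diff(tab$aic) >= 0))
  expect_equal(tab$k[tab$variant == "split_threshold"],
               tab$k[tab$variant == "shared_threshold"] + 1)
  # identical variants yield identical rows
  tab2 <- compare_models(tr, variants = list(
    a = list(t_exec_free = TRUE), b = list(t_exec_free = TRUE)),
    config = cfg)
  expect_equal(tab2$aic[1], tab2$aic[2])
})

test_that("data generated without a threshold split prefer the simpler model", {
  # nested-variant parsimony: with a_diff = 0 in truth, the shared-threshold
  # model should win or tie (within the 2-unit parameter penalty) most times
  cfg <- fit_config(n_sims = 800, n_hops = 1, maxit = 150, restarts = 2,
                    seed = 9)
  wins <- 0L
  n_rep <- 6
  for (r in seq_len(n_rep)) {
    tr <- simulate_trials(control_params(), 80, 80, seed = 670 + r)
    tab <- compare_models(tr, variants = list(
      shared = list(a_diff_free = FALSE),
      split = list(a_diff_free = TRUE)), config = cfg)
    a_shared <- tab$aic[tab$variant == "shared"]
    a_split <- tab$aic[tab$variant == "split"]
    if (a_shared <= a_split + 2) wins <- wins + 1L
  }
  expect_gte(wins, 0.8 * n_rep)
})

test_that("estimation error shrinks as trials per subject grow", {
  rng <- default_recovery_ranges()
  truths <- waldrace:::with_seed(71, lapply(1:10, function(i) {
    x <- vapply(rng, function(r) runif(1, r[1], r[2]), numeric(1))
    race_params(x["v_pre"], x["v_inhib"], x["v_exec"], x["a_mean"],
                x["t"], x["t_exec"])
  }))
  cfg <- fit_config(n_sims = 1000, n_hops = 1, maxit = 250, restarts = 2,
                    seed = 12)
  mae_at <- function(n_trials) {
    err <- vapply(seq_along(truths), function(i) {
      tr <- simulate_trials(truths[[i]], n_trials, n_trials,
                            seed = 700 + i)
      f <- suppressWarnings(fit_subject(tr, cfg))
      abs(f$params_hat$v_exec - truths[[i]]$v_exec)
    }, numeric(1))
    mean(err)
  }
  expect_lt(mae_at(250), mae_at(30))
})

test_that("a planted group difference in executive drift is recovered in sign", {
  base <- control_params()
  lower <- race_params(base$v_pre, base$v_inhib, base$v_exec - 2.2,
                       base$a_mean, base$t, base$t_exec)
  cfg <- test_fit_config(seed = 10)
  est <- sapply(1:4, function(i) {
    p <- if (i <= 2) base else lower
    f <- fit_subject(simulate_trials(p, 150, 150, seed = 680 + i), cfg)
    f$params_hat$v_exec
  })
  expect_gt(mean(est[1:2]), mean(est[3:4]))
})
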