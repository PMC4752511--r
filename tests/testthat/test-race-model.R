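test_that("parameter validation enforces the model invariants", {
  expect_s3_class(reference_params(), "race_params")
  expect_error(race_params(-1, 4, 6, 1.5, 0.2, 0.1), "positive")
  expect_error(race_params(8, 4, 6, 0, 0.2, 0.1), "positive")
  expect_error(race_params(8, 4, 6, 1.5, -0.1, 0.1), "non-negative")
  # a_diff large enough to push a threshold non-positive
  expect_error(race_params(8, 4, 6, 1, 0.2, 0.1, a_diff = 2.5), "threshold")
})

test_that("prosaccade trials are always correct with rt above t", {
  p <- reference_params()
  tr <- simulate_trials(p, n_pro = 500, n_anti = 0, seed = 2)
  expect_equal(nrow(tr), 500)
  expect_true(all(tr$response == "correct"))
  expect_true(all(tr$rt_seconds > p$t))
})

test_that("near-instant inhibition makes almost every anti trial correct", {
  p <- race_params(8, 1e4, 6, a_mean = 1.5, t = 0.2, t_exec = 0.1)
  out <- race_anti(p, crn_draws(1e5, seed = 4))
  expect_gte(mean(out$response == "correct"), 0.999)
})

test_that("deterministic executive limit pins the correct-anti RT mean", {
  # with v_exec -> inf, correct RT -> t + t_exec + a / v_exec
  p <- race_params(1, 0.5, 1e3, a_mean = 1.5, t = 0.2, t_exec = 0.5)
  out <- race_anti(p, crn_draws(1e5, seed = 6))
  rt_c <- out$rt_seconds[out$response == "correct"]
  expect_equal(mean(rt_c), 0.7015, tolerance = 0.005 / 0.7015)
})

test_that("simulated sessions are reproducible and sized exactly", {
  p <- reference_params()
  expect_equal(nrow(simulate_trials(p, 0, 0, seed = 1)), 0)
  a <- simulate_trials(p, 30, 40, seed = 9)
  b <- simulate_trials(p, 30, 40, seed = 9)
  expect_identical(a, b)
  expect_equal(sum(a$trial_type == "pro"), 30)
  expect_equal(sum(a$trial_type == "anti"), 40)
})

test_that("anti error rate at reference parameters matches the large-n oracle", {
  # frozen pre-build constant from an independent 1e5-trial simulation
  out <- race_anti(reference_params(), crn_draws(1e5, seed = 11))
  expect_equal(mean(out$response == "error"), 0.887, tolerance = 0.012)
  expect_gt(mean(out$response == "error"), 0)
  expect_lt(mean(out$response == "error"), 1)
})

test_that("simulated prosaccade RTs match the analytic shifted CDF", {
  p <- reference_params()
  tr <- simulate_trials(p, n_pro = 1e5, n_anti = 0, seed = 12)
  ks <- suppressWarnings(
    ks.test(tr$rt_seconds - p$t, function(q) pwald(q, p$v_pre, p$a_mean)))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("error rate is monotone in each drift under common random numbers", {
  d <- crn_draws(4000, seed = 13)
  base <- reference_params()
  err_rate <- function(p) mean(race_anti(p, d)$response == "error")
  modify <- function(field, value) {
    q <- unclass(base); q[[field]] <- value
    do.call(race_params, q[c("v_pre", "v_inhib", "v_exec", "a_mean",
                             "t", "t_exec", "a_diff")])
  }
  # nonincreasing in inhibitory and executive drift
  for (field in c("v_inhib", "v_exec")) {
    rates <- sapply(c(2, 4, 8, 16), function(v) err_rate(modify(field, v)))
    expect_true(all(diff(rates) <= 0), info = field)
  }
  # nondecreasing in prepotent drift and executive delay
  rates <- sapply(c(2, 4, 8, 16), function(v) err_rate(modify("v_pre", v)))
  expect_true(all(diff(rates) >= 0))
  rates <- sapply(c(0, 0.1, 0.2, 0.4),
                  function(v) err_rate(modify("t_exec", v)))
  expect_true(all(diff(rates) >= 0))
})

test_that("inhibition censors errors without touching correct-anti RTs", {
  d <- crn_draws(4000, seed = 14)
  p1 <- reference_params()
  p2 <- race_params(p1$v_pre, 2 * p1$v_inhib, p1$v_exec, p1$a_mean,
                    p1$t, p1$t_exec)
  s1 <- race_anti(p1, d)
  s2 <- race_anti(p2, d)
  expect_lt(sum(s2$response == "error"), sum(s1$response == "error"))
  both <- s1$response == "correct" & s2$response == "correct"
  expect_true(any(both))
  expect_identical(s1$rt_seconds[both], s2$rt_seconds[both])
})

test_that("executive delay shifts every correct-anti RT by exactly delta", {
  d <- crn_draws(4000, seed = 15)
  delta <- 0.07
  p1 <- reference_params()
  p2 <- race_params(p1$v_pre, p1$v_inhib, p1$v_exec, p1$a_mean,
                    p1$t, p1$t_exec + delta)
  s1 <- race_anti(p1, d)
  s2 <- race_anti(p2, d)
  # a longer delay can only add errors, and trials still correct under the
  # longer delay were correct before, shifted forward by exactly delta
  expect_gte(sum(s2$response == "error"), sum(s1$response == "error"))
  still <- s2$response == "correct"
  expect_true(all(s1$response[still] == "correct"))
  expect_equal(s2$rt_seconds[still], s1$rt_seconds[still] + delta,
               tolerance = 1e-12)
})

test_that("a_diff = 0 reduces the two-threshold variant to the shared model", {
  d <- crn_draws(2000, seed = 16)
  p1 <- reference_params()
  p2 <- race_params(p1$v_pre, p1$v_inhib, p1$v_exec, p1$a_mean, p1$t,
                    p1$t_exec, a_diff = 0)
  expect_identical(race_anti(p1, d), race_anti(p2, d))
  rts <- c(0.3, 0.4, 0.5)
  expect_identical(prosaccade_loglik(p1, rts), prosaccade_loglik(p2, rts))
})

test_that("prosaccade log-likelihood matches the closed form", {
  p <- race_params(1, 4, 6, a_mean = 1, t = 0.2, t_exec = 0.1)
  expect_equal(prosaccade_loglik(p, 1.2), log(1 / sqrt(2 * pi)))
  expect_identical(prosaccade_loglik(p, numeric(0)), 0)
  expect_error(prosaccade_loglik(p, c(0.5, -1)), "positive")
  # an RT at or below t hits the density floor, not -Inf
  expect_equal(prosaccade_loglik(p, 0.1), log(1e-10))
})

test_that("true prosaccade parameters dominate perturbed ones", {
  p <- reference_params()
  wins <- 0L
  for (r in 1:100) {
    tr <- simulate_trials(p, n_pro = 200, n_anti = 0, seed = 500 + r)
    ll_true <- prosaccade_loglik(p, tr$rt_seconds)
    up <- race_params(1.5 * p$v_pre, p$v_inhib, p$v_exec, p$a_mean, p$t,
                      p$t_exec)
    dn <- race_params(0.5 * p$v_pre, p$v_inhib, p$v_exec, p$a_mean, p$t,
                      p$t_exec)
    if (ll_true >= prosaccade_loglik(up, tr$rt_seconds) &&
        ll_true >= prosaccade_loglik(dn, tr$rt_seconds)) wins <- wins + 1L
  }
  expect_gte(wins, 95)
})
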