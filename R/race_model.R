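#' Parameters of the antisaccade race model
#'
#' Bundles and validates the parameters of the three-accumulator race model.
#' A prepotent accumulator (drift `v_pre`) drives the reflexive saccade
#' towards the stimulus; an inhibitory accumulator (drift `v_inhib`, also
#' called the stop process) can suppress it; an executive-control accumulator
#' (drift `v_exec`), starting after a fixed delay `t_exec`, drives the
#' voluntary saccade away from the stimulus. All accumulators share the
#' condition threshold. On prosaccade trials only the prepotent process runs.
#'
#' The two-threshold variant allows the antisaccade threshold to differ from
#' the prosaccade one: the effective thresholds are
#' `a_pro = a_mean - a_diff / 2` and `a_anti = a_mean + a_diff / 2`.
#' With `a_diff = 0` the model reduces exactly to a single shared threshold.
#'
#' @param v_pre,v_inhib,v_exec drift rates (evidence units per second, > 0).
#' @param a_mean mean decision threshold (evidence units, > 0).
#' @param t non-decision time in seconds (>= 0): sensory and motor latency
#'   added to every reaction time.
#' @param t_exec fixed onset delay of the executive accumulator in seconds
#'   (>= 0), capturing rule retrieval and saccade-vector inversion.
#' @param a_diff threshold difference between anti and pro conditions
#'   (default 0, the single-threshold model). Both effective thresholds must
#'   remain strictly positive.
#' @return an object of class `race_params` (a named list).
#' @examples
#' p <- race_params(v_pre = 8, v_inhib = 4, v_exec = 6,
#'                  a_mean = 1.5, t = 0.2, t_exec = 0.1)
#' p
#' @export
race_params <- function(v_pre, v_inhib, v_exec, a_mean, t, t_exec,
                        a_diff = 0) {
  p <- list(v_pre = v_pre, v_inhib = v_inhib, v_exec = v_exec,
            a_mean = a_mean, a_diff = a_diff, t = t, t_exec = t_exec)
  validate_race_params(p)
  structure(p, class = "race_params")
}

param_names <- function() {
  c("v_pre", "v_inhib", "v_exec", "a_mean", "a_diff", "t", "t_exec")
}

validate_race_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in param_names())
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite scalar",
                             call. = FALSE)
  if (p$v_pre <= 0 || p$v_inhib <= 0 || p$v_exec <= 0)
    stop("all drift rates must be strictly positive", call. = FALSE)
  if (p$a_mean <= 0)
    stop("'a_mean' must be strictly positive", call. = FALSE)
  if (a_pro(p) <= 0 || a_anti(p) <= 0)
    stop("effective thresholds a_mean -/+ a_diff/2 must be strictly positive",
         call. = FALSE)
  if (p$t < 0 || p$t_exec < 0)
    stop("'t' and 't_exec' must be non-negative", call. = FALSE)
  invisible(p)
}

a_pro <- function(p) p$a_mean - p$a_diff / 2
a_anti <- function(p) p$a_mean + p$a_diff / 2

#' @export
print.race_params <- function(x, ...) {
  cat("Antisaccade race-model parameters\n")
  cat(sprintf("  drifts      v_pre = %.3f  v_inhib = %.3f  v_exec = %.3f\n",
              x$v_pre, x$v_inhib, x$v_exec))
  cat(sprintf("  threshold   a_mean = %.3f  a_diff = %.3f  (a_pro = %.3f, a_anti = %.3f)\n",
              x$a_mean, x$a_diff, a_pro(x), a_anti(x)))
  cat(sprintf("  timing      t = %.3f s  t_exec = %.3f s\n", x$t, x$t_exec))
  invisible(x)
}

#' @export
as.data.frame.race_params <- function(x, ...) {
  as.data.frame(unclass(x)[param_names()])
}

#' Common-random-number draws for antisaccade simulation
#'
#' Pre-generates the underlying standard-normal and uniform variates consumed
#' by [race_anti()]: one (z, u) pair per accumulator per trial, in fixed
#' order. Reusing one `crn_draws` object across parameter settings makes
#' counterfactual comparisons exact ("common random numbers"): e.g. changing
#' `v_inhib` alters only the inhibitory finishing times while the prepotent
#' and executive finishing times stay bit-identical.
#'
#' @param n number of antisaccade trials.
#' @param seed integer seed.
#' @return an object of class `crn_draws`.
#' @export
crn_draws <- function(n, seed) {
  stopifnot(n >= 1)
  with_seed(seed, {
    z <- matrix(rnorm(3 * n), nrow = n,
                dimnames = list(NULL, c("pre", "inhib", "exec")))
    u <- matrix(runif(3 * n), nrow = n,
                dimnames = list(NULL, c("pre", "inhib", "exec")))
    structure(list(z = z, u = u, n = n, seed = seed), class = "crn_draws")
  })
}

#' Run the antisaccade race on fixed underlying draws
#'
#' The core race logic. Each trial draws three finishing times:
#' `T_pre` and `T_inhib` from the prepotent and inhibitory accumulators, and
#' `T_exec = t_exec + FPT(v_exec)` from the delayed executive accumulator,
#' all racing towards the antisaccade threshold. An error (reflexive saccade
#' towards the stimulus) occurs only when the prepotent process beats *both*
#' the inhibitory and the executive process; otherwise the trial resolves as
#' a correct antisaccade at the executive finishing time. Requiring the
#' prepotent process to also beat the executive one prevents arbitrarily slow
#' inhibition from producing errors slower than the executed correct
#' response. Ties (probability zero for continuous draws) resolve in favour
#' of inhibition.
#'
#' @param params a [race_params()] object.
#' @param draws a [crn_draws()] object.
#' @return a data frame with columns `response` ("correct"/"error") and
#'   `rt_seconds` (> `t`), one row per trial.
#' @export
race_anti <- function(params, draws) {
  validate_race_params(params)
  stopifnot(inherits(draws, "crn_draws"))
  a <- a_anti(params)
  t_pre <- wald_transform(draws$z[, "pre"], draws$u[, "pre"], params$v_pre, a)
  t_inh <- wald_transform(draws$z[, "inhib"], draws$u[, "inhib"],
                          params$v_inhib, a)
  t_exe <- params$t_exec +
    wald_transform(draws$z[, "exec"], draws$u[, "exec"], params$v_exec, a)
  err <- t_pre < t_inh & t_pre < t_exe
  data.frame(response = ifelse(err, "error", "correct"),
             rt_seconds = params$t + ifelse(err, t_pre, t_exe))
}

#' Simulate a pro/antisaccade session
#'
#' Draws `n_pro` prosaccade and `n_anti` antisaccade trials from the race
#' model and returns them in randomly interleaved order, as in the task.
#' Prosaccade trials use the prepotent accumulator alone and are always
#' correct (prosaccade errors are rare in practice and not modelled).
#'
#' @param params a [race_params()] object.
#' @param n_pro,n_anti trial counts (>= 0).
#' @param seed integer seed; the output is deterministic given the seed.
#' @return a data frame with columns `trial_type` ("pro"/"anti"), `response`
#'   and `rt_seconds`.
#' @examples
#' p <- race_params(8, 4, 6, a_mean = 1.5, t = 0.2, t_exec = 0.1)
#' head(simulate_trials(p, n_pro = 5, n_anti = 5, seed = 1))
#' @export
simulate_trials <- function(params, n_pro, n_anti, seed) {
  validate_race_params(params)
  stopifnot(n_pro >= 0, n_anti >= 0)
  n <- n_pro + n_anti
  if (n == 0)
    return(data.frame(trial_type = character(), response = character(),
                      rt_seconds = numeric()))
  with_seed(seed, {
    pro <- if (n_pro > 0) {
      data.frame(trial_type = "pro", response = "correct",
                 rt_seconds = params$t +
                   wald_transform(rnorm(n_pro), runif(n_pro),
                                  params$v_pre, a_pro(params)))
    }
    anti <- if (n_anti > 0) {
      d <- crn_draws_local(n_anti)
      cbind(trial_type = "anti", race_anti(params, d))
    }
    out <- rbind(pro, anti)
    out <- out[sample.int(n), , drop = FALSE]
    rownames(out) <- NULL
    out[, c("trial_type", "response", "rt_seconds")]
  })
}

# Allocation-light race used inside likelihood evaluation: consumes the
# current RNG stream and returns plain vectors (rt, err). Same race logic as
# race_anti().
race_anti_raw <- function(params, n) {
  a <- a_anti(params)
  z <- rnorm(3 * n)
  u <- runif(3 * n)
  i1 <- seq_len(n); i2 <- n + i1; i3 <- 2L * n + i1
  t_pre <- wald_transform(z[i1], u[i1], params$v_pre, a)
  t_inh <- wald_transform(z[i2], u[i2], params$v_inhib, a)
  t_exe <- params$t_exec + wald_transform(z[i3], u[i3], params$v_exec, a)
  err <- t_pre < t_inh & t_pre < t_exe
  rt <- t_exe
  rt[err] <- t_pre[err]
  list(rt = params$t + rt, err = err)
}

# crn_draws without reseeding: consumes the current RNG stream.
crn_draws_local <- function(n) {
  z <- matrix(rnorm(3 * n), nrow = n,
              dimnames = list(NULL, c("pre", "inhib", "exec")))
  u <- matrix(runif(3 * n), nrow = n,
              dimnames = list(NULL, c("pre", "inhib", "exec")))
  structure(list(z = z, u = u, n = n, seed = NA), class = "crn_draws")
}

#' Closed-form prosaccade log-likelihood
#'
#' Prosaccade reaction times are modelled by the prepotent accumulator alone,
#' whose first-passage law has the closed-form Wald density. The
#' log-likelihood of a set of prosaccade RTs is the sum of shifted log
#' densities `log f(rt - t; v_pre, a_pro)`. Densities below `floor`
#' (including RTs at or below the non-decision time `t`) contribute
#' `log(floor)` so the objective stays finite everywhere.
#'
#' @param params a [race_params()] object.
#' @param pro_rts vector of prosaccade RTs in seconds (> 0); may be empty,
#'   in which case the log-likelihood is 0.
#' @param floor density floor applied before taking logs.
#' @return the summed log-likelihood (finite scalar).
#' @export
prosaccade_loglik <- function(params, pro_rts, floor = 1e-10) {
  validate_race_params(params)
  if (length(pro_rts) == 0) return(0)
  if (any(pro_rts <= 0)) stop("prosaccade RTs must be positive", call. = FALSE)
  sum(log(pmax(dwald(pro_rts - params$t, params$v_pre, a_pro(params)),
               floor)))
}
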