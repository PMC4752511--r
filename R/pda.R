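#' Build a simulated (PDA) likelihood for antisaccade trials
#'
#' The antisaccade likelihood of the race model has no closed form, so it is
#' approximated by probability density approximation (PDA): simulate many
#' trials at the candidate parameter setting, split them by response channel
#' (correct vs error), and fit one Gaussian kernel density per channel with
#' Silverman's rule-of-thumb bandwidth. Each channel density is *defective*:
#' it is weighted by the simulated channel probability, so the two channels
#' jointly integrate to one.
#'
#' A channel with fewer than two simulated trials is degenerate: evaluating
#' it returns the density floor rather than raising an error, so extreme
#' parameter settings remain comparable during optimization.
#'
#' @param params a [race_params()] object.
#' @param n_sims number of simulated trials (>= 100; 10000 is the default
#'   used for fitting, smaller values trade accuracy for speed).
#' @param seed integer seed; the approximation is deterministic given
#'   (params, n_sims, seed).
#' @param condition `"anti"` (the default) builds the two-channel defective
#'   likelihood from antisaccade simulations; `"pro"` builds a single-channel
#'   likelihood from the prepotent accumulator alone, which is useful for
#'   checking the kernel approximation against the closed-form prosaccade
#'   likelihood.
#' @param floor density floor shared with the rest of the objective.
#' @return an object of class `pda_likelihood` with elements `p_correct`,
#'   `n_sims`, `bandwidths`, `seed`, the per-channel simulated RTs and
#'   density grids.
#' @export
build_pda <- function(params, n_sims = 10000, seed = 1,
                      condition = c("anti", "pro"), floor = 1e-10) {
  validate_race_params(params)
  condition <- match.arg(condition)
  if (n_sims < 100) stop("'n_sims' must be at least 100", call. = FALSE)
  sims <- with_seed(seed, {
    if (condition == "anti") {
      race_anti_raw(params, n_sims)
    } else {
      list(rt = params$t + wald_transform(rnorm(n_sims), runif(n_sims),
                                          params$v_pre, a_pro(params)),
           err = rep(FALSE, n_sims))
    }
  })
  rt_c <- sims$rt[!sims$err]
  rt_e <- sims$rt[sims$err]
  bw_c <- channel_bw(rt_c)
  bw_e <- channel_bw(rt_e)
  structure(list(
    p_correct = length(rt_c) / n_sims,
    rt_correct = rt_c, rt_error = rt_e,
    kde_correct = channel_kde(rt_c, bw_c),
    kde_error = channel_kde(rt_e, bw_e),
    bandwidths = c(correct = bw_c, error = bw_e),
    n_sims = n_sims, seed = seed, condition = condition, floor = floor),
    class = "pda_likelihood")
}

# Gaussian KDE with Silverman bandwidth, stored as a fine grid for fast
# interpolation. cut = 4 keeps the truncated tail mass below 1e-4 so the
# defective densities still integrate to one within quadrature tolerance.
channel_kde <- function(x, bw) {
  if (length(x) < 2 || is.na(bw) || bw <= 0) return(NULL)
  stats::density(x, bw = bw, n = 1024, cut = 4)
}

channel_bw <- function(x) {
  if (length(x) < 2 || stats::sd(x) == 0) return(NA_real_)
  stats::bw.nrd0(x)
}

# Kernel density evaluated by interpolating the FFT grid; a degenerate
# channel (fewer than two simulated trials) evaluates to zero and is caught
# by the floor downstream. Queries beyond the grid (4 bandwidths past the
# simulated extremes) carry negligible kernel mass and evaluate to zero.
eval_channel <- function(kde, rt) {
  if (is.null(kde)) return(numeric(length(rt)))
  stats::approx(kde$x, kde$y, xout = rt, yleft = 0, yright = 0)$y
}

#' @export
print.pda_likelihood <- function(x, ...) {
  cat(sprintf("PDA likelihood (%s): %d simulations, p_correct = %.3f\n",
              x$condition, x$n_sims, x$p_correct))
  invisible(x)
}

#' Antisaccade log-likelihood under a PDA approximation
#'
#' Sums, over observed antisaccade trials, the log of the defective channel
#' density at the trial's RT: `log(p_channel * kde_channel(rt))`, floored so
#' observations outside the simulated support (or in a degenerate channel)
#' contribute `log(floor)` rather than `-Inf`.
#'
#' @param pda a [build_pda()] object.
#' @param trials data frame with columns `response` ("correct"/"error") and
#'   `rt_seconds` (> 0); may have zero rows (log-likelihood 0).
#' @return finite summed log-likelihood.
#' @export
anti_loglik <- function(pda, trials) {
  stopifnot(inherits(pda, "pda_likelihood"))
  if (nrow(trials) == 0) return(0)
  if (any(trials$rt_seconds <= 0))
    stop("RTs must be positive", call. = FALSE)
  lik <- numeric(nrow(trials))
  ok_c <- trials$response == "correct"
  lik[ok_c] <- pda$p_correct *
    eval_channel(pda$kde_correct, trials$rt_seconds[ok_c])
  lik[!ok_c] <- (1 - pda$p_correct) *
    eval_channel(pda$kde_error, trials$rt_seconds[!ok_c])
  sum(log(pmax(lik, pda$floor)))
}

#' Total subject log-likelihood (closed-form pro + PDA anti)
#'
#' Combines the closed-form prosaccade likelihood with the simulated
#' antisaccade likelihood for one subject's trials. Prosaccade trials
#' constrain `v_pre`, the threshold and `t`; antisaccade trials additionally
#' constrain `v_inhib`, `v_exec` and `t_exec`. With a fixed `seed` the value
#' is a deterministic function of the parameters, which keeps the
#' optimization objective well behaved despite the simulation step.
#'
#' @param params a [race_params()] object.
#' @param trials data frame with columns `trial_type` ("pro"/"anti"),
#'   `response` and `rt_seconds`; must contain at least one trial.
#' @param n_sims simulations per evaluation (passed to [build_pda()]).
#' @param seed simulation seed.
#' @param floor shared density floor.
#' @return finite summed log-likelihood.
#' @export
total_loglik <- function(params, trials, n_sims = 10000, seed = 1,
                         floor = 1e-10) {
  if (nrow(trials) == 0)
    stop("subject has no trials", call. = FALSE)
  pro <- trials[trials$trial_type == "pro", , drop = FALSE]
  anti <- trials[trials$trial_type == "anti", , drop = FALSE]
  ll <- prosaccade_loglik(params, pro$rt_seconds, floor = floor)
  if (nrow(anti) > 0) {
    pda <- build_pda(params, n_sims = n_sims, seed = seed, floor = floor)
    ll <- ll + anti_loglik(pda, anti)
  }
  ll
}
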