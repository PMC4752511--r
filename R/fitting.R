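#' Fitting configuration
#'
#' Collects everything that determines a per-subject fit: simulation effort,
#' basin-hopping schedule, parameter bounds, model variant and the seed that
#' makes the whole fit deterministic.
#'
#' Model variants toggle which parameters are free: `a_diff_free` releases
#' the anti-vs-pro threshold difference (otherwise fixed at 0, the shared
#' single-threshold model) and `t_exec_free` releases the executive onset
#' delay (otherwise fixed at 0). The number of free parameters `k` feeds the
#' AIC in [compare_models()].
#'
#' @param n_sims simulated trials per objective evaluation (default 10000;
#'   2000 is a reasonable fast profile).
#' @param n_hops basin-hopping restarts around the best point found so far.
#' @param maxit Nelder-Mead iteration cap per local search.
#' @param restarts Nelder-Mead rounds per hop. The likelihood surface has a
#'   pronounced threshold-drift ridge along which a single simplex tends to
#'   collapse; re-starting the simplex at the incumbent is what lets the
#'   local search actually descend the ridge.
#' @param seed integer seed controlling both the simulation stream inside the
#'   objective and the basin-hopping proposals.
#' @param a_diff_free,t_exec_free model-variant flags (see Details).
#' @param bounds named list of `c(lower, upper)` bounds; see
#'   [default_bounds()]. `a_diff` is parametrized internally as a fraction of
#'   `a_mean` in (-0.5, 0.5) so both effective thresholds stay positive.
#' @param step_frac basin-hopping perturbation scale as a fraction of each
#'   bound range.
#' @param floor density floor shared across the objective.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(n_sims = 10000, n_hops = 3, maxit = 500,
                       restarts = 3, seed = 1,
                       a_diff_free = FALSE, t_exec_free = TRUE,
                       bounds = default_bounds(), step_frac = 0.25,
                       floor = 1e-10) {
  stopifnot(n_sims >= 100, n_hops >= 1, maxit >= 10, restarts >= 1)
  structure(list(n_sims = n_sims, n_hops = n_hops, maxit = maxit,
                 restarts = restarts, seed = as.integer(seed),
                 a_diff_free = a_diff_free,
                 t_exec_free = t_exec_free, bounds = bounds,
                 step_frac = step_frac, floor = floor),
            class = "fit_config")
}

#' Default parameter bounds for fitting
#'
#' Box bounds covering physiological saccade latencies with margin: drifts in
#' (0.1, 40], threshold in (0.3, 5], non-decision time in \[0.05, 0.6\] s and
#' executive delay in \[0, 0.6\] s. The threshold difference is bounded as a
#' fraction of `a_mean` (|a_diff| <= a_mean / 2).
#'
#' @return named list of `c(lower, upper)` pairs.
#' @export
default_bounds <- function() {
  list(v_pre = c(0.1, 40), v_inhib = c(0.1, 40), v_exec = c(0.1, 40),
       a_mean = c(0.3, 5), a_diff_frac = c(-0.49, 0.49),
       t = c(0.05, 0.6), t_exec = c(0, 0.6))
}

# logistic map between the bounded natural scale and the unconstrained
# optimization scale; the optimizer can therefore never leave the box.
to_unconstrained <- function(x, lo, hi) {
  p <- pmin(pmax((x - lo) / (hi - lo), 1e-6), 1 - 1e-6)
  qlogis(p)
}
to_bounded <- function(theta, lo, hi) lo + (hi - lo) * plogis(theta)

free_param_names <- function(config) {
  nm <- c("v_pre", "v_inhib", "v_exec", "a_mean", "t")
  if (config$a_diff_free) nm <- c(nm, "a_diff_frac")
  if (config$t_exec_free) nm <- c(nm, "t_exec")
  nm
}

vec_to_params <- function(x, config) {
  g <- function(nm, default) if (nm %in% names(x)) unname(x[nm]) else default
  a_mean <- unname(x["a_mean"])
  race_params(v_pre = unname(x["v_pre"]), v_inhib = unname(x["v_inhib"]),
              v_exec = unname(x["v_exec"]), a_mean = a_mean,
              t = unname(x["t"]),
              t_exec = g("t_exec", 0),
              a_diff = g("a_diff_frac", 0) * a_mean)
}

#' Fit the race model to one subject by simulated maximum likelihood
#'
#' Maximizes [total_loglik()] over the bounded parameter space. The fit runs
#' in three stages. First the prosaccade parameters (`v_pre`, `a_mean`, `t`)
#' are estimated on prosaccade trials alone using the closed-form likelihood,
#' initialized by moment matching (`t0 = 0.9 * min(pro RT)`, threshold/drift
#' ratio matched to the mean shifted RT). Second, the antisaccade-only
#' parameters (`v_inhib`, `v_exec`, `t_exec`) are optimized with the
#' prosaccade triple held at its stage-one estimate, which gives the joint
#' stage a start already close to the surface's ridge. Third, all free
#' parameters are optimized jointly with Nelder-Mead on a
#' logistic-transformed scale inside a basin-hopping loop: each hop runs
#' `restarts` simplex rounds from the incumbent, perturbation hops displace
#' the incumbent by `step_frac` of each bound range, and the best point
#' across hops is returned. The simulation seed is fixed for the whole fit,
#' so the objective is deterministic and refitting with the same
#' configuration reproduces the estimate exactly.
#'
#' @param trials one subject's trials: data frame with columns `trial_type`,
#'   `response`, `rt_seconds`. Subjects with fewer than 20 pro or 20 anti
#'   trials are fit anyway but flagged with a low-data warning.
#' @param config a [fit_config()] object.
#' @return an object of class `race_fit`: `params_hat`, `loglik`, `n_evals`,
#'   `n_hops`, `n_sims`, `seed`, `converged`, `low_data` and trial counts.
#' @export
fit_subject <- function(trials, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  pro <- trials[trials$trial_type == "pro", , drop = FALSE]
  anti <- trials[trials$trial_type == "anti", , drop = FALSE]
  if (nrow(trials) == 0) stop("subject has no trials", call. = FALSE)
  low_data <- nrow(pro) < 20 || nrow(anti) < 20
  if (low_data)
    warning("fewer than 20 pro or anti trials; estimates may be unstable",
            call. = FALSE)
  b <- config$bounds

  init <- pro_stage_init(pro$rt_seconds, config)

  free <- free_param_names(config)
  lo <- vapply(b[free], `[`, numeric(1), 1)
  hi <- vapply(b[free], `[`, numeric(1), 2)
  start <- c(v_pre = init["v_pre"], v_inhib = init["v_pre"],
             v_exec = init["v_pre"], a_mean = init["a_mean"],
             a_diff_frac = 0, t = init["t"], t_exec = 0.05)
  names(start) <- c("v_pre", "v_inhib", "v_exec", "a_mean", "a_diff_frac",
                    "t", "t_exec")
  start <- pmin(pmax(start[free], lo + 1e-6 * (hi - lo)),
                hi - 1e-6 * (hi - lo))

  n_evals <- 0L
  obj <- function(theta) {
    n_evals <<- n_evals + 1L
    x <- to_bounded(theta, lo, hi)
    names(x) <- free
    p <- vec_to_params(x, config)
    -total_loglik(p, trials, n_sims = config$n_sims, seed = config$seed,
                  floor = config$floor)
  }

  # local search = repeated Nelder-Mead rounds from the incumbent; the
  # simplex is re-inflated each round so the search can track the ridge.
  local_search <- function(theta, rounds) {
    fit <- stats::optim(theta, obj, method = "Nelder-Mead",
                        control = list(maxit = config$maxit,
                                       reltol = 1e-9))
    for (r in seq_len(rounds - 1)) {
      nxt <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                          control = list(maxit = config$maxit,
                                         reltol = 1e-9))
      improved <- nxt$value < fit$value - 0.01
      if (nxt$value < fit$value) fit <- nxt
      if (!improved) break
    }
    fit
  }

  best <- NULL
  with_seed(config$seed + 1L, {
    # stage two: anti-only parameters with the prosaccade triple fixed
    if (nrow(anti) > 0) {
      anti_free <- intersect(free, c("v_inhib", "v_exec", "t_exec"))
      if (length(anti_free) > 0) {
        fixed <- start[setdiff(free, anti_free)]
        lo_a <- lo[anti_free]; hi_a <- hi[anti_free]
        obj_a <- function(th) {
          x <- c(fixed, to_bounded(th, lo_a, hi_a))
          names(x) <- c(names(fixed), anti_free)
          p <- vec_to_params(x[free], config)
          n_evals <<- n_evals + 1L
          -total_loglik(p, trials, n_sims = config$n_sims,
                        seed = config$seed, floor = config$floor)
        }
        fa <- stats::optim(to_unconstrained(start[anti_free], lo_a, hi_a),
                           obj_a, method = "Nelder-Mead",
                           control = list(maxit = 300))
        start[anti_free] <- to_bounded(fa$par, lo_a, hi_a)
      }
    }
    # stage three: joint basin-hopping
    for (hop in seq_len(config$n_hops)) {
      th <- if (hop == 1) to_unconstrained(start, lo, hi) else {
        x_best <- to_bounded(best$par, lo, hi)
        x_new <- pmin(pmax(x_best + runif(length(lo), -1, 1) *
                             config$step_frac * (hi - lo),
                           lo + 1e-6 * (hi - lo)), hi - 1e-6 * (hi - lo))
        to_unconstrained(x_new, lo, hi)
      }
      fit <- local_search(th, config$restarts)
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    # final polish at the overall incumbent; a polish that no longer moves
    # the objective is the convergence signal
    pre_polish <- best$value
    best <- local_search(best$par, config$restarts)
    best$converged <- (pre_polish - best$value) < 0.1
    best
  }) -> best

  x_hat <- to_bounded(best$par, lo, hi)
  names(x_hat) <- free
  structure(list(params_hat = vec_to_params(x_hat, config),
                 loglik = -best$value,
                 n_evals = n_evals, n_hops = config$n_hops,
                 n_sims = config$n_sims, seed = config$seed,
                 converged = best$converged, low_data = low_data,
                 n_pro = nrow(pro), n_anti = nrow(anti),
                 free = free),
            class = "race_fit")
}

# Closed-form prosaccade pre-fit: cheap and stabilizes v_pre, a_mean, t
# before the simulated joint stage.
pro_stage_init <- function(pro_rts, config) {
  b <- config$bounds
  if (length(pro_rts) < 3) {
    return(c(v_pre = 8, a_mean = 1.5, t = 0.2))
  }
  t0 <- max(b$t[1], min(0.9 * min(pro_rts), b$t[2]))
  a0 <- 1.2
  v0 <- min(max(a0 / max(mean(pro_rts) - t0, 0.02), b$v_pre[1] * 2),
            b$v_pre[2] / 2)
  lo <- c(b$v_pre[1], b$a_mean[1], b$t[1])
  hi <- c(b$v_pre[2], b$a_mean[2], b$t[2])
  start <- pmin(pmax(c(v0, a0, t0), lo + 1e-6), hi - 1e-6)
  nll <- function(theta) {
    x <- to_bounded(theta, lo, hi)
    p <- race_params(v_pre = x[1], v_inhib = 1, v_exec = 1, a_mean = x[2],
                     t = x[3], t_exec = 0)
    -prosaccade_loglik(p, pro_rts, floor = config$floor)
  }
  fit <- stats::optim(to_unconstrained(start, lo, hi), nll,
                      method = "Nelder-Mead", control = list(maxit = 300))
  x <- to_bounded(fit$par, lo, hi)
  c(v_pre = x[1], a_mean = x[2], t = x[3])
}

#' @export
print.race_fit <- function(x, ...) {
  cat(sprintf("Race-model fit: loglik = %.2f (%d evaluations, %d hops%s)\n",
              x$loglik, x$n_evals, x$n_hops,
              if (x$converged) "" else ", not converged"))
  print(x$params_hat)
  invisible(x)
}

#' Parameter-recovery study
#'
#' Generative validation of the estimator: draw true parameter sets from wide
#' plausible ranges, simulate a session per synthetic subject, refit each
#' subject, and tabulate truth against estimate. Per-parameter Pearson
#' correlations and mean bias summarize identifiability. When the true
#' values of a parameter have zero variance its correlation is undefined and
#' reported as `NA`.
#'
#' @param n_subjects number of synthetic subjects (>= 5 recommended).
#' @param n_pro,n_anti trials per subject.
#' @param ranges named list of `c(lower, upper)` sampling ranges for each
#'   parameter (defaults to [default_recovery_ranges()]); a degenerate range
#'   (`lower == upper`) fixes the parameter.
#' @param config a [fit_config()] used for every fit.
#' @param seed seed for drawing truths and simulating sessions.
#' @return an object of class `recovery_report`: `$table` has one row per
#'   subject-parameter pair (`subject`, `param`, `truth`, `estimate`);
#'   `$summary` has per-parameter `cor` and `bias`; failures are recorded
#'   per subject in `$errors` without aborting the batch.
#' @export
recover_parameters <- function(n_subjects = 20, n_pro = 200, n_anti = 200,
                               ranges = default_recovery_ranges(),
                               config = fit_config(), seed = 1) {
  stopifnot(n_subjects >= 1)
  truths <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      x <- vapply(ranges, function(r) runif(1, r[1], r[2]), numeric(1))
      race_params(v_pre = x["v_pre"], v_inhib = x["v_inhib"],
                  v_exec = x["v_exec"], a_mean = x["a_mean"], t = x["t"],
                  t_exec = x["t_exec"],
                  a_diff = if ("a_diff" %in% names(x)) x["a_diff"] else 0)
    })
  })
  rows <- list()
  errors <- list()
  for (i in seq_len(n_subjects)) {
    trials <- simulate_trials(truths[[i]], n_pro, n_anti,
                              seed = seed + 1000L + i)
    est <- tryCatch(
      suppressWarnings(fit_subject(trials, config))$params_hat,
      error = function(e) e)
    if (inherits(est, "error")) {
      errors[[as.character(i)]] <- conditionMessage(est)
      next
    }
    for (nm in param_names()) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = i, param = nm, truth = truths[[i]][[nm]],
        estimate = est[[nm]])
    }
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$param), function(d) {
    r <- if (stats::sd(d$truth) == 0 || stats::sd(d$estimate) == 0)
      NA_real_ else stats::cor(d$truth, d$estimate)
    data.frame(param = d$param[1], cor = r,
               bias = mean(d$estimate - d$truth),
               n = nrow(d))
  }))
  rownames(summ) <- NULL
  structure(list(table = tab, summary = summ, errors = errors,
                 n_subjects = n_subjects, n_pro = n_pro, n_anti = n_anti,
                 seed = seed),
            class = "recovery_report")
}

#' Plausible parameter ranges for recovery studies
#'
#' Ranges spanning the behavioural regimes real subjects produce in this
#' task -- antisaccade accuracies from roughly 30% to 90% -- while staying
#' inside the fitting bounds. Settings whose error rate approaches 100%
#' leave almost no correct antisaccades and would make the executive drift
#' unidentifiable by construction, so they are excluded from the plausible
#' set.
#'
#' @return named list of `c(lower, upper)` pairs.
#' @export
default_recovery_ranges <- function() {
  list(v_pre = c(5, 8), v_inhib = c(5, 11), v_exec = c(4, 9),
       a_mean = c(1.0, 1.8), t = c(0.12, 0.22), t_exec = c(0.04, 0.14))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d subjects, %d pro + %d anti trials each\n",
              x$n_subjects, x$n_pro, x$n_anti))
  print(x$summary, row.names = FALSE)
  if (length(x$errors))
    cat(sprintf("  %d subject(s) failed to fit\n", length(x$errors)))
  invisible(x)
}

#' @export
plot.recovery_report <- function(x, params = c("v_pre", "v_inhib", "v_exec"),
                                 ...) {
  op <- graphics::par(mfrow = c(1, length(params)))
  on.exit(graphics::par(op))
  for (nm in params) {
    d <- x$table[x$table$param == nm, ]
    graphics::plot(d$truth, d$estimate, xlab = "true", ylab = "estimated",
                   main = nm, ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Compare model variants by AIC
#'
#' Fits each variant (a list of flag overrides for [fit_config()], e.g.
#' `list(a_diff_free = TRUE)`) to the same subject and ranks them by
#' `AIC = 2k - 2 loglik`, where `k` counts the free parameters. Lower AIC
#' indicates a better parsimony/fit trade-off.
#'
#' @param trials one subject's trials.
#' @param variants named list of variant flag lists; at least two.
#' @param config base [fit_config()] shared by all variants.
#' @return data frame with columns `variant`, `k`, `loglik`, `aic`, sorted
#'   by ascending AIC.
#' @export
compare_models <- function(trials, variants, config = fit_config()) {
  stopifnot(length(variants) >= 2)
  rows <- lapply(names(variants), function(nm) {
    cfg <- config
    for (fl in names(variants[[nm]])) cfg[[fl]] <- variants[[nm]][[fl]]
    fit <- suppressWarnings(fit_subject(trials, cfg))
    k <- length(fit$free)
    data.frame(variant = nm, k = k, loglik = fit$loglik,
               aic = 2 * k - 2 * fit$loglik)
  })
  out <- do.call(rbind, rows)
  out[order(out$aic), , drop = FALSE]
}

#' Fit every subject in a cohort trial table
#'
#' Convenience wrapper running [fit_subject()] per subject and returning one
#' row of fitted parameters per subject, ready to merge with clinical data.
#'
#' @param trials trial table with a `subject_id` column.
#' @param config a [fit_config()]; each subject's objective seed is offset
#'   from `config$seed` by its position so fits are independent yet
#'   reproducible.
#' @param progress print one line per subject.
#' @return data frame: `subject_id`, fitted parameter columns, `loglik`,
#'   `converged`.
#' @export
fit_cohort <- function(trials, config = fit_config(), progress = FALSE) {
  ids <- unique(trials$subject_id)
  rows <- lapply(seq_along(ids), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    fit <- suppressWarnings(
      fit_subject(trials[trials$subject_id == ids[i], , drop = FALSE], cfg))
    if (progress)
      message(sprintf("fit %s (%d/%d): loglik %.1f", ids[i], i, length(ids),
                      fit$loglik))
    cbind(data.frame(subject_id = ids[i]),
          as.data.frame(fit$params_hat),
          data.frame(loglik = fit$loglik, converged = fit$converged))
  })
  do.call(rbind, rows)
}
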