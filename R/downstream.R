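#' Ordinary least squares with staging-style reporting
#'
#' Least-squares regression of a response on a table of predictors, wrapping
#' [stats::lm()], reporting the quantities used in the staging analyses:
#' coefficients, R-squared, adjusted R-squared, the overall F statistic with
#' degrees of freedom, and AIC/BIC. Rows with missing values are dropped
#' listwise before fitting.
#'
#' @param x data frame (or matrix) of predictors, one row per subject.
#' @param y numeric response.
#' @return an object of class `ols_fit`: `coefficients`, `r_squared`,
#'   `adj_r_squared`, `f_statistic`, `df` (model, residual), `p_value`,
#'   `aic`, `bic`, `n` and the underlying `lm` object in `$model`.
#' @export
ols_fit <- function(x, y) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y))
  keep <- stats::complete.cases(x) & !is.na(y)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  if (nrow(x) < ncol(x) + 2)
    stop("need more observations than predictors", call. = FALSE)
  d <- cbind(.response = y, x)
  fit <- stats::lm(.response ~ ., data = d)
  if (fit$rank < ncol(x) + 1)
    stop("rank-deficient design: drop collinear or constant predictors",
         call. = FALSE)
  s <- summary(fit)
  fstat <- unname(s$fstatistic)
  structure(list(
    coefficients = stats::coef(fit),
    r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
    f_statistic = fstat[1], df = c(model = fstat[2], residual = fstat[3]),
    p_value = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    aic = stats::AIC(fit), bic = stats::BIC(fit),
    n = nrow(x), model = fit), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS: n = %d, R-squared = %.3f (adj. %.3f), F(%d, %d) = %.2f, p = %.3g\n",
              x$n, x$r_squared, x$adj_r_squared, x$df[1], x$df[2],
              x$f_statistic, x$p_value))
  print(round(x$coefficients, 4))
  invisible(x)
}

hinge <- function(x, knot) pmax(0, x - knot)

#' Piecewise-linear breakpoint regression (single-predictor MARS)
#'
#' Searches for breakpoints in the relationship between a single predictor
#' and a response by forward selection over hinge terms `max(0, x - knot)`,
#' with candidate knots at the interior quantiles of the observed predictor
#' values, pruned by generalized cross-validation
#' `GCV = (RSS / n) / (1 - C(M) / n)^2` with effective model cost
#' `C(M) = p + penalty * n_knots`. The base model is the ordinary line; a
#' hinge is retained only when it lowers the GCV, so an exactly linear
#' relationship keeps no hinge and a flat response keeps neither slope nor
#' hinges. Used here to ask whether a fitted model parameter declines
#' linearly across disease stages or only after a breakpoint stage.
#'
#' @param x single numeric predictor (at least 20 observations, not
#'   constant).
#' @param y numeric response.
#' @param max_hinges maximum number of hinge terms (default 2).
#' @param penalty GCV cost per knot (default 3, the usual choice for
#'   additive hinge models).
#' @return an object of class `hinge_fit`: `intercept`, `slope`, `knots`,
#'   `hinge_slopes`, `gcv`, `n`.
#' @export
mars_fit <- function(x, y, max_hinges = 2, penalty = 3) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 20) stop("need at least 20 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant predictor: no breakpoint is defined",
                              call. = FALSE)
  n <- length(x)
  gcv_of <- function(fit, n_knots) {
    rss <- sum(stats::residuals(fit)^2)
    cm <- length(stats::coef(fit)) + penalty * n_knots
    if (cm >= n) return(Inf)
    (rss / n) / (1 - cm / n)^2
  }
  # candidate knots at observed predictor values (interior only), thinned
  # to at most ~60 by quantile when x is dense
  cand <- sort(unique(x))
  cand <- cand[cand > min(x) & cand < max(x)]
  if (length(cand) > 60)
    cand <- unique(stats::quantile(cand, probs = seq(0.02, 0.98,
                                                     length.out = 60),
                                   names = FALSE, type = 1))

  base <- stats::lm(y ~ x)
  best <- list(fit = base, knots = numeric(0), gcv = gcv_of(base, 0))
  if (length(cand) > 0) {
    for (step in seq_len(max_hinges)) {
      incumbent <- best
      trial_best <- NULL
      for (k in setdiff(cand, incumbent$knots)) {
        knots <- c(incumbent$knots, k)
        H <- sapply(knots, function(kk) hinge(x, kk))
        fit <- stats::lm(y ~ x + H)
        if (anyNA(stats::coef(fit))) next
        g <- gcv_of(fit, length(knots))
        if (is.null(trial_best) || g < trial_best$gcv)
          trial_best <- list(fit = fit, knots = knots, gcv = g)
      }
      if (is.null(trial_best) || trial_best$gcv >= incumbent$gcv - 1e-12)
        break
      best <- trial_best
    }
  }
  cf <- stats::coef(best$fit)
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2]),
                 knots = unname(best$knots),
                 hinge_slopes = if (length(best$knots)) unname(cf[-(1:2)])
                                else numeric(0),
                 gcv = best$gcv, n = n), class = "hinge_fit")
}

#' @export
print.hinge_fit <- function(x, ...) {
  cat(sprintf("Piecewise-linear fit (n = %d): y = %.3f + %.3f x", x$n,
              x$intercept, x$slope))
  if (length(x$knots))
    cat(paste0(sprintf(" + %.3f h(x - %.3f)", x$hinge_slopes, x$knots),
               collapse = ""))
  cat(sprintf("\n  GCV = %.4g, %d knot(s)\n", x$gcv, length(x$knots)))
  invisible(x)
}

#' @export
predict.hinge_fit <- function(object, newdata, ...) {
  out <- object$intercept + object$slope * newdata
  for (i in seq_along(object$knots))
    out <- out + object$hinge_slopes[i] * hinge(newdata, object$knots[i])
  out
}

#' Regression of disease stage on fitted model parameters
#'
#' Multiple linear regression of the linearly coded disease stage
#' (controls = 0 through most affected = 4) on the fitted race-model
#' parameters, mirroring the staging analysis: a parameter that tracks
#' progression receives a non-zero coefficient, and the executive drift is
#' expected to carry a negative one.
#'
#' @param subjects data frame with a `stage` column and parameter columns.
#' @param params which parameter columns to include.
#' @return an [ols_fit()] object.
#' @export
stage_regression <- function(subjects,
                             params = c("v_pre", "v_inhib", "v_exec",
                                        "a_mean", "t", "t_exec")) {
  params <- intersect(params, names(subjects))
  keep <- params[vapply(subjects[params],
                        function(x) stats::sd(x, na.rm = TRUE) > 0,
                        logical(1))]
  ols_fit(subjects[keep], subjects$stage)
}

#' Regressions of clinical scores on fitted parameters
#'
#' Regresses the log-transformed total motor score (`log(TMS + 1)`, the
#' offset admitting the zero scores typical of controls), the total
#' functional capacity (TFC) and the CAG repeat length each on the fitted
#' model parameters, and additionally reports the simple slope of `v_exec`
#' on log-TMS (expected negative: worse motor scores go with slower
#' executive accumulation).
#'
#' @param subjects data frame with parameter columns and clinical columns
#'   `tms`, `tfc`, `cag` (missing scores are dropped listwise per model).
#' @param params parameter columns used as predictors.
#' @return list with `ols_fit` entries `tms`, `tfc`, `cag` and the scalar
#'   `vexec_on_log_tms_slope`.
#' @export
clinical_regressions <- function(subjects,
                                 params = c("v_pre", "v_inhib", "v_exec",
                                            "a_mean", "t", "t_exec")) {
  params <- intersect(params, names(subjects))
  keep <- params[vapply(subjects[params],
                        function(x) stats::sd(x, na.rm = TRUE) > 0,
                        logical(1))]
  x <- subjects[keep]
  log_tms <- log(subjects$tms + 1)
  uni <- ols_fit(data.frame(log_tms = log_tms), subjects$v_exec)
  list(tms = ols_fit(x, log_tms),
       tfc = ols_fit(x, subjects$tfc),
       cag = ols_fit(x, subjects$cag),
       vexec_on_log_tms_slope = unname(uni$coefficients["log_tms"]))
}
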