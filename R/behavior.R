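#' Behavioural summary statistics for one subject
#'
#' Mean and sample SD of prosaccade RTs, of correct and of error antisaccade
#' RTs, plus antisaccade accuracy and per-cell trial counts. Cells with no
#' trials are reported as `NA` (missing), never as zero; accuracy requires at
#' least one antisaccade trial.
#'
#' @param trials data frame with columns `trial_type`, `response`,
#'   `rt_seconds`.
#' @return one-row data frame with columns `pro_rt_mean`, `pro_rt_sd`,
#'   `anti_correct_rt_mean`, `anti_correct_rt_sd`, `anti_error_rt_mean`,
#'   `anti_error_rt_sd`, `anti_accuracy`, `n_pro`, `n_anti`,
#'   `n_anti_correct`.
#' @export
summary_stats <- function(trials) {
  pro <- trials$rt_seconds[trials$trial_type == "pro"]
  anti <- trials[trials$trial_type == "anti", , drop = FALSE]
  if (nrow(anti) == 0)
    stop("antisaccade accuracy is undefined without anti trials",
         call. = FALSE)
  ac <- anti$rt_seconds[anti$response == "correct"]
  ae <- anti$rt_seconds[anti$response == "error"]
  cell <- function(x, f) if (length(x) == 0) NA_real_ else f(x)
  data.frame(
    pro_rt_mean = cell(pro, mean), pro_rt_sd = cell(pro, stats::sd),
    anti_correct_rt_mean = cell(ac, mean),
    anti_correct_rt_sd = cell(ac, stats::sd),
    anti_error_rt_mean = cell(ae, mean),
    anti_error_rt_sd = cell(ae, stats::sd),
    anti_accuracy = length(ac) / nrow(anti),
    n_pro = length(pro), n_anti = nrow(anti), n_anti_correct = length(ac))
}

#' The six delta-plot quantile ranges
#'
#' The conventional 0-10, 10-30, 30-50, 50-70, 70-90 and 90-100 percent
#' ranges used in distributional RT analysis.
#'
#' @return a 6 x 2 matrix of `lo`/`hi` quantile bounds.
#' @export
delta_ranges <- function() {
  cbind(lo = c(0, .1, .3, .5, .7, .9), hi = c(.1, .3, .5, .7, .9, 1))
}

#' Mean RT within quantile ranges
#'
#' Sorts the RTs, assigns the i-th of n order statistics the quantile
#' position (i - 0.5) / n, and averages the RTs whose positions fall in each
#' half-open range `[lo, hi)` (the last range is closed at 1). Ranges that
#' capture no trials are reported as `NA`.
#'
#' @param rts vector of RTs (at least one).
#' @param ranges matrix of quantile bounds as from [delta_ranges()].
#' @return numeric vector of per-range means, one per range row.
#' @export
quantile_range_means <- function(rts, ranges = delta_ranges()) {
  if (length(rts) == 0) stop("no RTs supplied", call. = FALSE)
  x <- sort(rts)
  pos <- (seq_along(x) - 0.5) / length(x)
  vapply(seq_len(nrow(ranges)), function(r) {
    lo <- ranges[r, 1]; hi <- ranges[r, 2]
    inside <- if (hi >= 1) pos >= lo & pos <= 1 else pos >= lo & pos < hi
    if (!any(inside)) NA_real_ else mean(x[inside])
  }, numeric(1))
}

#' Delta plot for one subject
#'
#' Distributional comparison of antisaccade against prosaccade RTs. For each
#' of the six quantile ranges, `y` is the anti-minus-pro difference in range
#' means (positive = conflict-induced slowing) and `x` is the average of the
#' two range means. Only correct antisaccade trials enter. A decreasing
#' y-over-range profile (negative delta-plot slope) indicates that conflict
#' is resolved as time passes. Subjects with fewer than 6 trials in either
#' condition yield missing points rather than an error.
#'
#' @param trials one subject's trials (`trial_type`, `response`,
#'   `rt_seconds`).
#' @return an object of classes `delta_plot`/`data.frame` with columns
#'   `range` ("0-10", ...), `x` and `y` (seconds).
#' @export
delta_plot <- function(trials) {
  pro <- trials$rt_seconds[trials$trial_type == "pro"]
  anti <- trials$rt_seconds[trials$trial_type == "anti" &
                              trials$response == "correct"]
  rng <- delta_ranges()
  lab <- paste0(rng[, 1] * 100, "-", rng[, 2] * 100)
  if (length(pro) < 6 || length(anti) < 6) {
    out <- data.frame(range = lab, x = NA_real_, y = NA_real_)
  } else {
    mp <- quantile_range_means(pro, rng)
    ma <- quantile_range_means(anti, rng)
    out <- data.frame(range = lab, x = (ma + mp) / 2, y = ma - mp)
  }
  class(out) <- c("delta_plot", "data.frame")
  out
}

#' Group-averaged delta plot
#'
#' Computes [delta_plot()] per subject and averages pointwise across the
#' subjects with complete points, with standard errors.
#'
#' @param trials cohort trial table with a `subject_id` column.
#' @return data frame with columns `range`, `x`, `y`, `se`, `n_subjects`.
#' @export
group_delta_plot <- function(trials) {
  per <- lapply(split(trials, trials$subject_id), delta_plot)
  keep <- Filter(function(d) !anyNA(d$y), per)
  if (length(keep) == 0) stop("no subject has complete delta-plot points",
                              call. = FALSE)
  xs <- sapply(keep, `[[`, "x")
  ys <- sapply(keep, `[[`, "y")
  data.frame(range = keep[[1]]$range,
             x = rowMeans(xs), y = rowMeans(ys),
             se = apply(ys, 1, stats::sd) / sqrt(length(keep)),
             n_subjects = length(keep))
}

#' @export
plot.delta_plot <- function(x, ...) {
  graphics::plot(x$x, x$y, type = "b", pch = 19,
                 xlab = "mean RT (s)", ylab = "anti - pro RT (s)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Two-sample comparison of a per-subject measure between groups
#'
#' Pooled-variance two-sample t test (Welch's correction behind a flag).
#' Degenerate inputs with zero variance in both groups and equal means
#' return `t = 0`; zero variance with unequal means is flagged as a
#' degenerate (infinite-statistic) comparison rather than an error.
#'
#' @param x,y numeric vectors, at least two observations each.
#' @param welch use Welch's unequal-variance test instead of the pooled one.
#' @return list with `statistic`, `df`, `p_value`, `degenerate`.
#' @export
group_compare <- function(x, y, welch = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, df = length(x) + length(y) - 2,
                  p_value = 1, degenerate = FALSE))
    return(list(statistic = Inf, df = length(x) + length(y) - 2,
                p_value = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, degenerate = FALSE)
}
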