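# Read-outs and statistics: windowed mean weights, the memory decision
# index, percentage baseline change, accuracy normalization and the
# least-squares model comparison.

#' Mean efficacy over a read-out window
#'
#' Arithmetic mean of an inter-subgroup mean-efficacy trajectory over a
#' closed time window; the standard read-out averages the auditory-to-visual
#' weights between 2.75 and 3 s after stimulus onset (one theta cycle).
#'
#' @param trajectory data frame with columns `time_ms` and the requested
#'   direction column (`rho_a2v` or `rho_v2a`), e.g. from
#'   [run_trial()]`$trajectory`
#' @param window length-2 numeric, closed window in ms (absolute trial time)
#' @param direction `"a2v"` (auditory to visual, the headline read-out) or
#'   `"v2a"`
#' @return mean efficacy over the window
#' @export
mean_weight_window <- function(trajectory, window = c(4750, 5000),
                               direction = c("a2v", "v2a")) {
  direction <- match.arg(direction)
  col <- paste0("rho_", direction)
  if (!col %in% names(trajectory)) stop("trajectory lacks column ", col)
  tms <- trajectory$time_ms
  if (window[1] < min(tms) || window[2] > max(tms))
    stop("read-out window [", window[1], ", ", window[2],
         "] lies outside the trajectory [", min(tms), ", ", max(tms), "]")
  keep <- tms >= window[1] & tms <= window[2]
  mean(trajectory[[col]][keep])
}

#' Memory decision index
#'
#' Converts pooled per-trial read-out values into recalled/forgotten calls:
#' the threshold is the 10th percentile of the pooled values (linear
#' interpolation between order statistics by default, `"nearest_rank"` as an
#' alternative) and a trial counts as recalled iff its value is strictly
#' above the threshold.  The pool must span all trials of the conditions
#' being compared (theta, delta, alpha and no-flicker).
#'
#' @param values pooled per-trial read-out values (at least 10)
#' @param prob percentile used for the threshold
#' @param method `"linear"` (interpolated) or `"nearest_rank"`
#' @return logical vector of recalled calls, same order as `values`, with
#'   the threshold attached as attribute `"threshold"`
#' @export
memory_decision_index <- function(values, prob = 0.10,
                                  method = c("linear", "nearest_rank")) {
  method <- match.arg(method)
  if (length(values) < 10)
    stop("at least 10 pooled trials are required to set the threshold")
  thr <- stats::quantile(values, prob,
                         type = if (method == "linear") 7 else 1,
                         names = FALSE)
  structure(values > thr, threshold = thr)
}

#' Percentage change relative to a baseline
#'
#' `100 * (post - baseline) / baseline`; undefined (NA with a warning) when
#' the baseline is zero.
#'
#' @param baseline_mean baseline-window mean efficacy (> 0)
#' @param post_mean post-window mean efficacy
#' @return percentage change
#' @export
percent_baseline_change <- function(baseline_mean, post_mean) {
  out <- ifelse(baseline_mean > 0,
                100 * (post_mean - baseline_mean) / baseline_mean, NA_real_)
  if (anyNA(out)) warning("zero baseline: percentage change undefined")
  out
}

#' Centre per-condition accuracies on their mean
#'
#' Normalizes a 4-condition accuracy (or simulated-weight) vector by
#' subtracting the mean over the four phase-offset conditions, making data
#' from different studies comparable; the output sums to zero.
#'
#' @param x numeric vector of length 4 (one value per phase-offset condition)
#' @return centred vector
#' @export
normalize_accuracy <- function(x) {
  if (length(x) != 4 || anyNA(x))
    stop("exactly the four phase-offset conditions must be present")
  x - mean(x)
}

#' Compare model variants against an empirical accuracy table
#'
#' Fits `empirical = a * simulated + b` by linear least squares for the full
#' model and one alternative variant over the four phase-offset conditions,
#' and compares the residual sums of squares with an F ratio
#' `F = ((RSS_variant - RSS_full) / 1) / (RSS_full / 3)` on (1, 3) degrees of
#' freedom, plus Gaussian BIC scores (`n log(RSS/n) + k log n`, n = 4,
#' k = 2 fitted coefficients).  The comparison is invariant to affine
#' rescaling of the simulated weights (absorbed by the fit).
#'
#' @param sim_full simulated 4-condition values of the full model
#' @param sim_variant simulated 4-condition values of the alternative variant
#' @param empirical empirical 4-condition accuracies (same offset order);
#'   either a numeric vector or a data frame with columns `offset` and
#'   `accuracy`
#' @param offsets phase offsets (degrees) labelling the four conditions
#' @return a list of class `model_comparison`: per-model RSS, fitted
#'   coefficients, `f_statistic` with degrees of freedom, p value, and BIC
#' @export
compare_models <- function(sim_full, sim_variant, empirical,
                           offsets = c(0, 90, 180, 270)) {
  if (is.data.frame(empirical)) {
    need <- c("offset", "accuracy")
    if (!all(need %in% names(empirical)))
      stop("empirical table needs columns 'offset' and 'accuracy'")
    if (!setequal(empirical$offset, offsets))
      stop("empirical table's offsets do not match the simulated conditions")
    empirical <- empirical$accuracy[match(offsets, empirical$offset)]
  }
  if (length(sim_full) != 4 || length(sim_variant) != 4 ||
      length(empirical) != 4)
    stop("one value per phase-offset condition is required for each model")
  fit <- function(sim) {
    m <- stats::lm(empirical ~ sim)
    list(coef = stats::coef(m), rss = sum(stats::residuals(m)^2))
  }
  ffull <- fit(sim_full)
  fvar <- fit(sim_variant)
  fstat <- ((fvar$rss - ffull$rss) / 1) / (ffull$rss / 3)
  bic <- function(rss, k = 2, n = 4) n * log(rss / n) + k * log(n)
  structure(list(
    rss_full = ffull$rss, rss_variant = fvar$rss,
    coef_full = ffull$coef, coef_variant = fvar$coef,
    f_statistic = fstat, df = c(1, 3),
    p_value = stats::pf(fstat, 1, 3, lower.tail = FALSE),
    bic_full = bic(ffull$rss), bic_variant = bic(fvar$rss),
    offsets = offsets), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Least-squares model comparison over", length(x$offsets),
      "phase-offset conditions\n")
  cat(sprintf("  RSS full = %.4g, RSS variant = %.4g\n",
              x$rss_full, x$rss_variant))
  cat(sprintf("  F(%d,%d) = %.2f, p = %.4f\n", x$df[1], x$df[2],
              x$f_statistic, x$p_value))
  cat(sprintf("  BIC full = %.2f, BIC variant = %.2f\n",
              x$bic_full, x$bic_variant))
  invisible(x)
}

#' Summarise per-trial read-outs by condition
#'
#' Across-trial mean and standard error of the read-out values per
#' condition.
#'
#' @param trials data frame of per-trial summaries (e.g. from
#'   [run_memory_grid()]) with a `condition` column
#' @param value name of the value column (default `"rho_a2v"`)
#' @return data frame with one row per condition: `mean`, `se`, `n`
#' @export
condition_summary <- function(trials, value = "rho_a2v") {
  sp <- split(trials[[value]], trials$condition)
  data.frame(condition = as.integer(names(sp)),
             mean = vapply(sp, mean, 0),
             se = vapply(sp, function(x) stats::sd(x) / sqrt(length(x)), 0),
             n = vapply(sp, length, 0L),
             row.names = NULL)
}
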