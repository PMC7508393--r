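#' Mean sensitivity of a ring-width series
#'
#' The classical dendrochronological indicator of year-to-year variability:
#' the average absolute width change between consecutive rings, relative to
#' the two rings' mean width,
#' \deqn{ms = \frac{1}{n_w-1}\sum_{i=1}^{n_w-1}
#'       \left|\frac{2(w_{i+1}-w_i)}{w_{i+1}+w_i}\right|.}
#' It is 0 for constant widths and 2 for rings alternating between zero and
#' positive width.
#'
#' @param widths Numeric vector of ring widths (cm), `n_w >= 2`.
#' @return Dimensionless value in \[0, 2\].
#' @export
mean_sensitivity <- function(widths) {
  terms <- sensitivity_terms(widths)
  mean(abs(terms))
}

# |2 (w_{i+1}-w_i) / (w_{i+1}+w_i)| for i = 1 .. n_w-1, with the undefined
# 0/0 case rejected
sensitivity_terms <- function(widths) {
  widths <- as.numeric(widths)
  n_w <- length(widths)
  if (n_w < 2L) stop("mean sensitivity needs at least two ring widths")
  num <- 2 * diff(widths)
  den <- widths[-n_w] + widths[-1]
  if (any(den == 0)) {
    stop("consecutive rings ", which(den == 0)[1], " and ",
         which(den == 0)[1] + 1L,
         " both have zero width; mean sensitivity is undefined")
  }
  num / den
}

#' Probabilistic mean sensitivity
#'
#' Each term of the classical mean sensitivity couples rings `i` and `i+1`
#' across their shared boundary (boundary `i`). When that boundary is annual
#' only with probability `P`, the term's expectation is the term times `P`,
#' giving
#' \deqn{\tilde{ms} = \frac{1}{n_w-1}\sum_{i=1}^{n_w-1}
#'       \left|P_{(i)}\frac{2(w_{i+1}-w_i)}{w_{i+1}+w_i}\right|,}
#' with \eqn{P_{(i)}} the input probability of the boundary between the two
#' rings. The variance follows from \eqn{E(X^2)-E(X)^2} with the same
#' weights; the standard error divides the variance by `n_w`, and the
#' confidence limits use the normal 1.96 multiplier (central limit theorem).
#'
#' @param widths Ring widths (cm), ordered by ring number.
#' @param boundary_probs Input probabilities for all `n_w + 1` boundaries of
#'   the series, starting with the base boundary's 1 (as returned by
#'   [boundary_probs()]).
#' @param level Confidence level for the normal-approximation interval.
#' @return A list with `ms_prob`, `ms_var`, `ms_se`, `ci_lower`, `ci_upper`.
#' @export
prob_mean_sensitivity <- function(widths, boundary_probs, level = 0.95) {
  terms <- sensitivity_terms(widths)
  n_w <- length(widths)
  p <- check_boundary_probs(boundary_probs, n_w)
  # term i couples w_i and w_{i+1}: the shared boundary is boundary i
  p_shared <- p[2:n_w]
  ms_prob <- mean(abs(p_shared * terms))
  ms_var <- mean(p_shared * terms^2) - ms_prob^2
  ms_se <- sqrt(ms_var / n_w)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(ms_prob = ms_prob, ms_var = ms_var, ms_se = ms_se,
       ci_lower = ms_prob - z * ms_se, ci_upper = ms_prob + z * ms_se)
}

check_boundary_probs <- function(p, n_w) {
  p <- as.numeric(p)
  if (length(p) != n_w + 1L) {
    stop("need one input probability per boundary (", n_w + 1L,
         " including the base), got ", length(p))
  }
  if (p[1] != 1) stop("the base boundary's probability must be 1")
  if (any(p <= 0) || any(p > 1)) stop("probabilities must lie in (0, 1]")
  p
}

#' Classical series statistics of ring widths
#'
#' `autocorrelation()` is the lag-1 autocorrelation of a stationary process,
#' computed about the plain arithmetic mean width; `ts_variance()` the
#' time-series variance with division by `n_w` (not `n_w - 1`); and
#' `process_sd()` the standard deviation of the underlying first-order
#' autoregressive (Markov) process,
#' \eqn{s_{proc} = \sqrt{s_{ts}^2/(1-r_{ac1}^2)}}, which combines variance and
#' persistence in one indicator.
#'
#' Widths are assumed stationary; see [detrend_check()] for an advisory test.
#'
#' @param widths Ring widths (cm), `n_w >= 3`.
#' @return `autocorrelation`: dimensionless in (-1, 1); `ts_variance`: cm^2;
#'   `process_sd`: cm.
#' @export
autocorrelation <- function(widths) {
  widths <- as.numeric(widths)
  n_w <- length(widths)
  if (n_w < 3L) stop("autocorrelation needs at least three ring widths")
  d <- widths - mean(widths)
  sum(d[-n_w] * d[-1]) / sum(d^2)
}

#' @rdname autocorrelation
#' @export
ts_variance <- function(widths) {
  widths <- as.numeric(widths)
  if (length(widths) < 2L) stop("variance needs at least two ring widths")
  mean((widths - mean(widths))^2)
}

#' @rdname autocorrelation
#' @export
process_sd <- function(widths) {
  r <- autocorrelation(widths)
  if (abs(r) >= 1) stop("process SD undefined for |autocorrelation| >= 1")
  sqrt(ts_variance(widths) / (1 - r^2))
}

#' Probabilistic series statistics of ring widths
#'
#' Probability-weighted versions of [autocorrelation()], [ts_variance()] and
#' [process_sd()]. In the autocorrelation numerator the cross term
#' \eqn{(w_i-\bar w)(w_{i+1}-\bar w)} is weighted by the probability of the
#' shared boundary between rings `i` and `i+1` (ring `i`'s outer boundary);
#' in the denominators each squared deviation \eqn{(w_i-\bar w)^2} is
#' weighted by ring `i`'s inner-boundary probability, so ring 1 carries the
#' base boundary's weight of 1. The mean \eqn{\bar w} is the unweighted
#' arithmetic mean throughout. Weighted statistics are never larger than the
#' classical ones and coincide with them when every probability is 1.
#'
#' @inheritParams prob_mean_sensitivity
#' @return `prob_autocorrelation`: dimensionless; `prob_ts_variance`: cm^2;
#'   `prob_process_sd`: cm.
#' @export
prob_autocorrelation <- function(widths, boundary_probs) {
  widths <- as.numeric(widths)
  n_w <- length(widths)
  if (n_w < 3L) stop("autocorrelation needs at least three ring widths")
  p <- check_boundary_probs(boundary_probs, n_w)
  d <- widths - mean(widths)
  p_outer <- p[2:n_w]       # boundary between rings i and i+1
  p_inner <- p[1:n_w]       # ring i's inner boundary (ring 1 -> base, P = 1)
  sum(p_outer * d[-n_w] * d[-1]) / sum(p_inner * d^2)
}

#' @rdname prob_autocorrelation
#' @export
prob_ts_variance <- function(widths, boundary_probs) {
  widths <- as.numeric(widths)
  n_w <- length(widths)
  if (n_w < 2L) stop("variance needs at least two ring widths")
  p <- check_boundary_probs(boundary_probs, n_w)
  d <- widths - mean(widths)
  mean(p[1:n_w] * d^2)
}

#' @rdname prob_autocorrelation
#' @export
prob_process_sd <- function(widths, boundary_probs) {
  r <- prob_autocorrelation(widths, boundary_probs)
  if (abs(r) >= 1) stop("process SD undefined for |autocorrelation| >= 1")
  sqrt(prob_ts_variance(widths, boundary_probs) / (1 - r^2))
}

#' Advisory stationarity check before autocorrelation
#'
#' Ordinary least-squares regression of width on ring number. A significant
#' slope indicates an age trend in the widths, in which case standardization
#' is recommended before interpreting the autoregressive statistics. The
#' check is advisory: nothing is detrended automatically.
#'
#' @param widths Ring widths (cm).
#' @param alpha Significance level for the slope.
#' @return A list with `slope` (cm per ring), `p_value` and `significant`.
#' @export
detrend_check <- function(widths, alpha = 0.05) {
  widths <- as.numeric(widths)
  if (stats::var(widths) == 0) {
    return(list(slope = 0, p_value = NA_real_, significant = FALSE))
  }
  ring <- seq_along(widths)
  fit <- stats::lm(widths ~ ring)
  cf <- summary(fit)$coefficients
  slope <- unname(cf["ring", "Estimate"])
  p_value <- unname(cf["ring", "Pr(>|t|)"])
  list(slope = slope, p_value = p_value,
       significant = is.finite(p_value) && p_value < alpha)
}

#' All series statistics for a ring series
#'
#' Convenience wrapper computing the classical and probabilistic mean
#' sensitivity, lag-1 autocorrelation, time-series variance and process
#' standard deviation for one series. Warns when the advisory trend check
#' flags a significant width trend.
#'
#' @param series A [ring_series()] with all widths available.
#' @param level Confidence level for the mean-sensitivity interval.
#' @return An object of class `series_stats`: a list with elements `ms`,
#'   `ms_prob`, `ms_var`, `ms_se`, `ms_ci_lower`, `ms_ci_upper`, `r_ac1`,
#'   `r_ac1_prob`, `s_ts2`, `s_ts2_prob`, `s_proc`, `s_proc_prob`, `n_w`,
#'   `trend_slope`, `trend_p_value`.
#' @export
series_stats <- function(series, level = 0.95) {
  stopifnot(inherits(series, "ring_series"))
  w <- ring_widths(series)
  if (anyNA(w)) stop("series_stats() needs a width for every ring")
  p <- boundary_probs(series)
  ms <- mean_sensitivity(w)
  pms <- prob_mean_sensitivity(w, p, level)
  trend <- detrend_check(w)
  if (trend$significant) {
    warning(sprintf(
      "widths show a significant linear trend (slope %.3g cm/ring, p = %.3g); consider standardizing before interpreting autoregressive statistics",
      trend$slope, trend$p_value))
  }
  out <- list(
    ms = ms,
    ms_prob = pms$ms_prob, ms_var = pms$ms_var, ms_se = pms$ms_se,
    ms_ci_lower = pms$ci_lower, ms_ci_upper = pms$ci_upper,
    r_ac1 = autocorrelation(w),
    r_ac1_prob = prob_autocorrelation(w, p),
    s_ts2 = ts_variance(w),
    s_ts2_prob = prob_ts_variance(w, p),
    s_proc = process_sd(w),
    s_proc_prob = prob_process_sd(w, p),
    n_w = length(w),
    trend_slope = trend$slope,
    trend_p_value = trend$p_value
  )
  class(out) <- "series_stats"
  out
}

#' @export
print.series_stats <- function(x, ...) {
  cat(sprintf("Series statistics (n_w = %d)\n", x$n_w))
  cat(sprintf("  mean sensitivity      ms  = %.3f   probabilistic = %.3f (SE %.4f, CI %.3f..%.3f)\n",
              x$ms, x$ms_prob, x$ms_se, x$ms_ci_lower, x$ms_ci_upper))
  cat(sprintf("  lag-1 autocorrelation r   = %.3f   probabilistic = %.3f\n",
              x$r_ac1, x$r_ac1_prob))
  cat(sprintf("  time-series variance  s2  = %.5f cm2 probabilistic = %.5f cm2\n",
              x$s_ts2, x$s_ts2_prob))
  cat(sprintf("  process SD            s   = %.4f cm  probabilistic = %.4f cm\n",
              x$s_proc, x$s_proc_prob))
  invisible(x)
}
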