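#' Interpolated inverse cumulative distribution function
#'
#' Although ages are modelled in whole years, time is continuous, so
#' non-integer confidence limits are meaningful. The discrete distribution is
#' turned into a continuous inverse CDF by connecting the knots
#' `(cumulative probability through age a, a)` — one knot per support age,
#' cumulative probability inclusive of the age's own mass — with straight
#' lines. For a quantile below the first knot's cumulative probability no
#' leftward interpolation exists; the lowest possible age is returned instead
#' (lower-bound substitution).
#'
#' @param dist An [age_distribution()].
#' @param q Quantile(s) in (0, 1).
#' @return Age(s) in years, possibly non-integer.
#' @export
inverse_cdf <- function(dist, q) {
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1)) {
    stop("'q' must lie strictly between 0 and 1")
  }
  cs <- cumsum(dist$probs)
  cs[length(cs)] <- 1  # guard against rounding at the top knot
  a <- ages(dist)
  vapply(q, function(qi) {
    i <- which(cs >= qi)[1]
    if (i == 1L) return(as.numeric(a[1]))
    a[i - 1L] + (qi - cs[i - 1L]) / (cs[i] - cs[i - 1L]) * (a[i] - a[i - 1L])
  }, numeric(1))
}

#' Confidence interval for a boundary's age
#'
#' Equal-tailed interval from the interpolated inverse CDF: the ages the
#' boundary would have with cumulative probability `(1-level)/2` and
#' `1-(1-level)/2`. The lower limit falls back to the lowest possible age
#' when the first support age already carries more than the lower tail mass.
#'
#' @param dist An [age_distribution()].
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Numeric vector `c(lower, upper)` in years.
#' @export
confidence_interval <- function(dist, level = 0.95) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  alpha <- (1 - level) / 2
  if (length(dist$probs) == 1L) {
    a <- as.numeric(ages(dist))
    return(c(lower = a, upper = a))
  }
  q <- inverse_cdf(dist, c(alpha, 1 - alpha))
  c(lower = q[1], upper = q[2])
}

#' Per-boundary age summary table
#'
#' Propagates the series and reports, for every boundary, its input
#' probability, the range of possible ages, the expected age, standard
#' deviation and confidence limits — the per-sample dating table of the
#' method.
#'
#' @param series A [ring_series()].
#' @param level Confidence level; default 0.95.
#' @param dists Optional precomputed result of `propagate(series)`.
#' @return A data frame with columns `boundary_index`, `p_annual`, `min_age`,
#'   `max_age`, `mean_age`, `sd_age`, `ci_lower`, `ci_upper`, carrying class
#'   `age_summary`.
#' @examples
#' s <- ring_series(c(1, rep(0.83, 48)))
#' tail(summarize_series(s), 1)  # mean 39.84, sd 2.602, CI (33.96, 44.10)
#' @export
summarize_series <- function(series, level = 0.95, dists = propagate(series)) {
  p <- boundary_probs(series)
  # theoretical possible-age range: every certain boundary adds a year to the
  # minimum, every boundary adds one to the maximum (which equals the index)
  min_possible <- c(0L, cumsum(p[-1] == 1))
  rows <- lapply(dists, function(d) {
    ci <- confidence_interval(d, level)
    data.frame(
      boundary_index = d$boundary_index,
      p_annual = NA_real_,
      min_age = min_possible[d$boundary_index + 1L],
      max_age = d$boundary_index,
      mean_age = mean_age(d),
      sd_age = sd_age(d),
      ci_lower = unname(ci[1]),
      ci_upper = unname(ci[2])
    )
  })
  out <- do.call(rbind, rows)
  out$p_annual <- p
  attr(out, "level") <- level
  class(out) <- c("age_summary", "data.frame")
  out
}

#' Radius-versus-age growth curve with confidence band
#'
#' Pairs each boundary's cumulative radius (the summed ring widths from the
#' base) with its expected age and confidence limits. The three
#' piecewise-linear curves (mean, lower, upper) share the radius axis and end
#' at the maximum measured radius — the curves are delimited horizontally at
#' that radius, not vertically at a maximum age. Zero-width rings (e.g.
#' inserted overlapping boundaries) produce consecutive points sharing a
#' radius, i.e. vertical steps in age.
#'
#' @param series A [ring_series()] whose widths are all available.
#' @param summaries Optional precomputed [summarize_series()] table.
#' @param level Confidence level, used when `summaries` is not supplied.
#' @return A data frame with columns `boundary_index`, `radius_cm`,
#'   `mean_age`, `ci_lower`, `ci_upper`.
#' @export
growth_curve <- function(series, summaries = NULL, level = 0.95) {
  w <- ring_widths(series)
  if (anyNA(w)) stop("growth_curve() needs a width for every ring")
  if (is.null(summaries)) summaries <- summarize_series(series, level)
  data.frame(
    boundary_index = summaries$boundary_index,
    radius_cm = c(0, cumsum(w)),
    mean_age = summaries$mean_age,
    ci_lower = summaries$ci_lower,
    ci_upper = summaries$ci_upper
  )
}
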