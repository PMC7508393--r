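#' Construct a discrete age distribution
#'
#' The age of a boundary, measured in whole years since the base boundary, is
#' a discrete random variable supported on consecutive integers
#' `t_min .. t_min + length(probs) - 1`. Probabilities must be non-negative
#' and sum to 1 (within 1e-9). Leading/trailing entries with negligible mass
#' (< 1e-15) are trimmed and the remainder renormalized, so the first and
#' last retained entries are always positive.
#'
#' @param probs Numeric probability vector over consecutive ages.
#' @param t_min Youngest age (in years) carried by `probs[1]`.
#' @param boundary_index Index of the boundary this distribution belongs to.
#' @return An object of class `age_distribution` with elements
#'   `boundary_index`, `t_min`, `probs`.
#' @export
age_distribution <- function(probs, t_min = 0L, boundary_index = NA_integer_) {
  probs <- as.numeric(probs)
  if (!length(probs)) stop("empty probability vector")
  if (any(!is.finite(probs)) || any(probs < -1e-12)) {
    stop("age probabilities must be finite and non-negative")
  }
  probs <- pmax(probs, 0)
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("age probabilities must sum to 1 (got ", format(sum(probs)), ")")
  }
  keep <- probs >= 1e-15
  first <- which(keep)[1]
  last <- which(keep)[sum(keep)]
  t_min <- as.integer(t_min) + first - 1L
  probs <- probs[first:last]
  probs <- probs / sum(probs)
  structure(
    list(boundary_index = as.integer(boundary_index),
         t_min = t_min, probs = probs),
    class = "age_distribution"
  )
}

#' @export
print.age_distribution <- function(x, ...) {
  cat(sprintf("Age distribution of boundary %s: ages %d..%d years\n",
              ifelse(is.na(x$boundary_index), "?", x$boundary_index),
              x$t_min, x$t_min + length(x$probs) - 1L))
  cat(sprintf("  mean %.4g, sd %.4g\n", mean_age(x), sd_age(x)))
  invisible(x)
}

#' Ages in the support of an age distribution
#' @param dist An `age_distribution`.
#' @return Integer vector of ages (years) with positive probability.
#' @export
ages <- function(dist) dist$t_min + seq_along(dist$probs) - 1L

#' Propagate input probabilities into age distributions
#'
#' Starting from a point mass at age 0 for the base boundary, the age
#' distribution of each successive boundary is obtained by convolving the
#' previous one with a Bernoulli one-year shift: with probability
#' `P[i+1]` boundary `i+1` is annual and every possible age advances by one
#' year; with probability `1 - P[i+1]` it is false and ages are unchanged,
#'
#' \deqn{L_{i+1,a} = (1-P_{i+1}) L_{i,a} + P_{i+1} L_{i,a-1}.}
#'
#' A boundary with `P = 1` shifts the whole support up by one year (the
#' youngest age's probability becomes exactly 0 and is trimmed). Missing
#' boundaries entered in the series take part in the identical recursion with
#' their own probability: if present, a missing boundary is necessarily
#' annual.
#'
#' @param series A [ring_series()].
#' @return A list of [age_distribution()] objects, one per boundary, in
#'   boundary order.
#' @examples
#' s <- ring_series(c(1, 0.7, 1, 0.2, 0.9),
#'                  type = c("base", "recognizable", "annual", "missing",
#'                           "recognizable"))
#' d <- propagate(s)
#' d[[4]]$probs  # boundary 3: ages 1..3 with probabilities 0.24, 0.62, 0.14
#' @export
propagate <- function(series) {
  stopifnot(inherits(series, "ring_series"))
  p <- boundary_probs(series)
  n_b <- length(p)
  out <- vector("list", n_b)
  L <- 1
  t_min <- 0L
  out[[1]] <- age_distribution(L, t_min, 0L)
  for (i in seq_len(n_b - 1L)) {
    pi1 <- p[i + 1L]
    L <- (1 - pi1) * c(L, 0) + pi1 * c(0, L)
    d <- age_distribution(L, t_min, i)
    # keep the trimmed representation for the next step
    L <- d$probs
    t_min <- d$t_min
    out[[i + 1L]] <- d
  }
  out
}

#' Closed-form age distribution for equal input probabilities
#'
#' When all uncertain boundaries share one probability `p`, the number of
#' annual boundaries among them is binomial, so the age distribution is
#' `base_age + Binomial(n_uncertain, p)`. Serves as the closed-form
#' cross-check for [propagate()].
#'
#' @param n_uncertain Number of boundaries with shared probability `p`.
#' @param p Shared input probability, in (0, 1].
#' @param base_age Certain age (years) contributed by `P = 1` boundaries.
#' @param boundary_index Optional boundary index to record.
#' @return An [age_distribution()].
#' @examples
#' binomial_ages(3, 0.83, base_age = 1)$probs  # 0.005, 0.072, 0.351, 0.572
#' @export
binomial_ages <- function(n_uncertain, p, base_age = 0L,
                          boundary_index = NA_integer_) {
  stopifnot(n_uncertain >= 0, p > 0, p <= 1)
  probs <- stats::dbinom(0:n_uncertain, n_uncertain, p)
  age_distribution(probs, base_age, boundary_index)
}

#' Moments of an age distribution
#'
#' `mean_age()` is the discrete expectation over the support,
#' `variance_age()` the corresponding variance
#' (\eqn{E(A^2) - E(A)^2}), and `sd_age()` its square root.
#'
#' @param dist An [age_distribution()].
#' @return Years (`mean_age`, `sd_age`) or squared years (`variance_age`).
#' @export
mean_age <- function(dist) sum(ages(dist) * dist$probs)

#' @rdname mean_age
#' @export
variance_age <- function(dist) {
  a <- ages(dist)
  m <- sum(a * dist$probs)
  max(sum(a^2 * dist$probs) - m^2, 0)
}

#' @rdname mean_age
#' @export
sd_age <- function(dist) sqrt(variance_age(dist))
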