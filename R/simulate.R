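#' Generate a random ring series
#'
#' Draws independent uniform input probabilities and ring widths for a series
#' of `n_boundaries` boundaries (the base boundary, with probability 1, plus
#' `n_boundaries - 1` recognizable ones). The defaults mirror the long
#' synthetic scenario used in the sensitivity analysis of the method:
#' probabilities uniform on \[0.5, 1\] and widths uniform on \[0, 0.5\] cm.
#'
#' @param n_boundaries Total number of boundaries including the base
#'   (`n_boundaries = 1` gives a base-only series).
#' @param p_range Length-2 range for the input probabilities; the lower end
#'   must be positive.
#' @param width_range Length-2 non-negative range for widths in cm.
#' @param seed Optional integer seed for reproducibility.
#' @param sample_id Sample label.
#' @return A [ring_series()].
#' @export
random_series <- function(n_boundaries, p_range = c(0.5, 1),
                          width_range = c(0, 0.5), seed = NULL,
                          sample_id = "simulated") {
  stopifnot(n_boundaries >= 1, length(p_range) == 2L,
            length(width_range) == 2L,
            p_range[1] > 0, p_range[2] <= 1, p_range[1] <= p_range[2],
            width_range[1] >= 0, width_range[1] <= width_range[2])
  if (!is.null(seed)) set.seed(seed)
  n <- n_boundaries - 1L
  ring_series(
    p_annual = c(1, stats::runif(n, p_range[1], p_range[2])),
    width_cm = if (n > 0L) stats::runif(n, width_range[1], width_range[2]) else NULL,
    sample_id = sample_id
  )
}

#' Sensitivity-analysis scenarios
#'
#' Builds the four standard perturbations of a case-study series used to
#' judge how strongly the dating results depend on the inputs:
#'
#' * `"a"` — missing boundaries: wide-ring outliers of the base series are
#'   split at their midpoints, each inserted boundary certain (`P = 1`);
#' * `"b"` — all post-base probabilities lowered to 0.5 (wider intervals,
#'   faster apparent growth);
#' * `"c"` — all post-base probabilities raised to 0.95 (narrower intervals,
#'   slower apparent growth);
#' * `"d"` — a long random series: 300 random boundaries plus the base, with
#'   probabilities uniform on \[0.5, 1\] and widths uniform on \[0, 0.5\] cm.
#'
#' @param scenario One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param base_series The case-study [ring_series()]; required for
#'   `"a"`–`"c"` (for `"a"` it must carry widths).
#' @param seed Seed for scenario `"d"`.
#' @param alpha Outlier level for scenario `"a"`.
#' @return A [ring_series()].
#' @examples
#' s <- ring_series(c(1, rep(0.83, 48)))
#' mean_age(propagate(make_scenario("c", s))[[49]])  # 45.6 years
#' @export
make_scenario <- function(scenario = c("a", "b", "c", "d"),
                          base_series = NULL, seed = NULL, alpha = 0.05) {
  scenario <- match.arg(scenario)
  if (scenario != "d" && !inherits(base_series, "ring_series")) {
    stop("scenarios a-c need a base series")
  }
  switch(scenario,
    a = {
      w <- ring_widths(base_series)
      if (anyNA(w)) stop("scenario 'a' needs ring widths")
      insert_missing(base_series, detect_wide_outliers(w, alpha), p = 1)
    },
    b = override_probs(base_series, 0.5),
    c = override_probs(base_series, 0.95),
    d = random_series(301L, seed = seed, sample_id = "scenario_d")
  )
}

# replace every post-base input probability by a constant
override_probs <- function(series, p) {
  b <- series$boundaries
  ring_series(
    p_annual = c(1, rep(p, nrow(b) - 1L)),
    width_cm = if (nrow(b) > 1L) b$width_cm[-1] else NULL,
    type = b$type,
    sample_id = series$sample_id
  )
}

#' Simulate realized boundary ages
#'
#' Samples the generative story the age-propagation recursion marginalizes:
#' each post-base boundary is independently annual with its input
#' probability, and a boundary's realized age is the number of annual
#' boundaries up to and including it. Used for Monte-Carlo checks such as
#' confidence-interval coverage, where the true ages are known by
#' construction.
#'
#' @param series A [ring_series()].
#' @param n_rep Number of replicate series to draw.
#' @param seed Optional integer seed.
#' @return An `n_rep` x `n_boundaries(series)` integer matrix of realized
#'   ages; column `j` holds boundary `j - 1`'s ages.
#' @export
simulate_true_ages <- function(series, n_rep = 1L, seed = NULL) {
  stopifnot(inherits(series, "ring_series"), n_rep >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- boundary_probs(series)[-1]
  n <- length(p)
  if (n == 0L) return(matrix(0L, nrow = n_rep, ncol = 1L))
  draws <- matrix(stats::rbinom(n_rep * n, 1L, rep(p, each = n_rep)),
                  nrow = n_rep, ncol = n)
  cbind(0L, t(apply(draws, 1L, cumsum)))
}
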