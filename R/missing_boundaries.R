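#' Expected number of missing boundaries
#'
#' Missing boundaries cannot be assigned a probability at an observed
#' location; instead one computes how many to expect from a frequency `F` of
#' missing boundaries per recognizable boundary (e.g. `F = 0.04` over 50
#' recognizable boundaries gives 2 expected missing boundaries). When the
#' expected count is below 0.5 the recommendation is to assume none.
#'
#' @param frequency Missing-boundary frequency `F >= 0` per recognizable
#'   boundary.
#' @param n_recognizable Number of recognizable boundaries.
#' @return A list with `expected_count` and logical `recommend_none`
#'   (`TRUE` when `expected_count < 0.5`).
#' @examples
#' expected_missing(0.04, 50)   # 2 expected
#' expected_missing(0.001, 48)  # ~0.05, recommend none
#' @export
expected_missing <- function(frequency, n_recognizable) {
  stopifnot(is.numeric(frequency), frequency >= 0,
            is.numeric(n_recognizable), n_recognizable >= 0)
  expected <- frequency * n_recognizable
  list(expected_count = expected, recommend_none = expected < 0.5)
}

#' Input probability for candidate missing boundaries
#'
#' When more candidate locations are suspected than boundaries are expected,
#' the expected count is split evenly: each inserted boundary gets probability
#' `expected_count / n_candidates`, capped at 1. Assigning exactly the
#' expected number gives each a probability of 1.
#'
#' @param expected_count Expected number of missing boundaries (> 0).
#' @param n_candidates Number of candidate locations (> 0).
#' @return Probability in (0, 1].
#' @examples
#' candidate_probability(2, 5)  # 0.4
#' candidate_probability(2, 2)  # 1
#' @export
candidate_probability <- function(expected_count, n_candidates) {
  stopifnot(is.numeric(expected_count), is.numeric(n_candidates))
  if (n_candidates <= 0) stop("'n_candidates' must be positive")
  p <- min(1, expected_count / n_candidates)
  if (p <= 0) {
    stop("expected count of 0 gives a zero input probability, which is not allowed")
  }
  p
}

#' Detect unusually wide rings
#'
#' Missing boundaries are suspected in unusually wide rings (two years of
#' growth appearing as one). The widths are studentized
#' (\eqn{(w-\bar w)/s}, sample standard deviation) and compared against a
#' t-distribution with `n_w - 1` degrees of freedom; rings whose tail
#' probability is below `alpha` are flagged. The default is the one-sided
#' upper tail; `two_sided = TRUE` also flags unusually narrow rings.
#'
#' @param widths Ring widths (cm), `n_w >= 3`.
#' @param alpha Significance level; default 0.05.
#' @param two_sided Flag both tails instead of only wide rings.
#' @return Integer vector of flagged ring numbers (possibly empty).
#' @export
detect_wide_outliers <- function(widths, alpha = 0.05, two_sided = FALSE) {
  widths <- as.numeric(widths)
  n_w <- length(widths)
  if (n_w < 3L) stop("outlier detection needs at least three ring widths")
  s <- stats::sd(widths)
  if (!is.finite(s) || s == 0) return(integer(0))
  z <- (widths - mean(widths)) / s
  df <- n_w - 1L
  p_tail <- if (two_sided) {
    2 * stats::pt(abs(z), df, lower.tail = FALSE)
  } else {
    stats::pt(z, df, lower.tail = FALSE)
  }
  which(p_tail < alpha)
}

#' Plan missing-boundary insertion for a series
#'
#' Combines [expected_missing()], [detect_wide_outliers()] and
#' [candidate_probability()]: the expected count comes from `frequency` times
#' the number of recognizable (non-base, non-missing) boundaries, candidate
#' rings are the wide outliers, and the expected count is split evenly over
#' them.
#'
#' @param series A [ring_series()] with widths.
#' @param frequency Missing-boundary frequency `F`.
#' @param alpha Outlier significance level.
#' @param two_sided Passed to [detect_wide_outliers()].
#' @return A list of class `missing_boundary_plan` with `frequency`,
#'   `expected_count`, `recommend_none`, `candidate_rings`,
#'   `per_candidate_p` (`NA` when there are no candidates or none are
#'   recommended).
#' @export
missing_boundary_plan <- function(series, frequency, alpha = 0.05,
                                  two_sided = FALSE) {
  stopifnot(inherits(series, "ring_series"))
  b <- series$boundaries
  n_rec <- sum(b$type == "recognizable")
  em <- expected_missing(frequency, n_rec)
  w <- ring_widths(series)
  cand <- if (anyNA(w)) integer(0) else detect_wide_outliers(w, alpha, two_sided)
  p <- if (length(cand) && em$expected_count > 0) {
    candidate_probability(em$expected_count, length(cand))
  } else {
    NA_real_
  }
  structure(
    list(frequency = frequency, expected_count = em$expected_count,
         recommend_none = em$recommend_none,
         candidate_rings = cand, per_candidate_p = p),
    class = "missing_boundary_plan"
  )
}

#' @export
print.missing_boundary_plan <- function(x, ...) {
  cat(sprintf("Missing-boundary plan: F = %g, expected count %.3g%s\n",
              x$frequency, x$expected_count,
              if (x$recommend_none) " (below 0.5: recommend assuming none)" else ""))
  if (length(x$candidate_rings)) {
    cat(sprintf("  candidate rings: %s (input probability %.3g each)\n",
                paste(x$candidate_rings, collapse = ", "), x$per_candidate_p))
  } else {
    cat("  no candidate rings\n")
  }
  invisible(x)
}

#' Insert missing boundaries into a series
#'
#' Each candidate ring of width `w` is split at its midpoint into two rings
#' of width `w/2`, separated by a new boundary of type `missing` with the
#' given input probability; boundaries are renumbered consecutively.
#' Downstream propagation treats the inserted boundary like any other. The
#' total radius is conserved exactly, and by the cumulative-probability
#' theorem the expected age of the final boundary grows by the sum of the
#' inserted probabilities.
#'
#' @param series A [ring_series()].
#' @param candidate_rings Ring numbers to split (a
#'   [missing_boundary_plan()] may be given instead, supplying both the rings
#'   and the probability).
#' @param p Input probability for each inserted boundary.
#' @param split Fraction of the ring width placed inside the new boundary;
#'   default 0.5 (equal halves).
#' @return A new, renumbered [ring_series()].
#' @export
insert_missing <- function(series, candidate_rings, p = 1, split = 0.5) {
  stopifnot(inherits(series, "ring_series"))
  if (inherits(candidate_rings, "missing_boundary_plan")) {
    plan <- candidate_rings
    candidate_rings <- plan$candidate_rings
    p <- plan$per_candidate_p
  }
  if (!length(candidate_rings)) return(series)
  stopifnot(split > 0, split < 1)
  candidate_rings <- sort(unique(as.integer(candidate_rings)))
  if (any(candidate_rings < 1L) || any(candidate_rings > n_widths(series))) {
    stop("candidate ring out of range 1..", n_widths(series))
  }
  b <- series$boundaries
  probs <- list(); types <- list(); widths <- list()
  for (i in seq_len(nrow(b))[-1]) {
    ring <- b$index[i]
    if (ring %in% candidate_rings) {
      w <- b$width_cm[i]
      probs[[length(probs) + 1L]] <- c(p, b$p_annual[i])
      types[[length(types) + 1L]] <- c("missing", b$type[i])
      widths[[length(widths) + 1L]] <- c(w * split, w * (1 - split))
    } else {
      probs[[length(probs) + 1L]] <- b$p_annual[i]
      types[[length(types) + 1L]] <- b$type[i]
      widths[[length(widths) + 1L]] <- b$width_cm[i]
    }
  }
  ring_series(
    p_annual = c(1, unlist(probs)),
    width_cm = unlist(widths),
    type = c("base", unlist(types)),
    sample_id = series$sample_id
  )
}
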