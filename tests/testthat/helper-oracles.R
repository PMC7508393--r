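# Independent oracles and fixture builders used across the test files.

# Exhaustive enumeration oracle for age propagation: every post-base boundary
# is independently annual (1) or false (0); a boundary's age is the number of
# annual boundaries up to it. Feasible for small series (2^(n_b-1) outcomes).
brute_force_distributions <- function(series) {
  p <- boundary_probs(series)[-1]
  n <- length(p)
  stopifnot(n <= 15)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  wts <- apply(grid, 1, function(g) prod(ifelse(g == 1, p, 1 - p)))
  lapply(0:n, function(i) {
    age <- if (i == 0) rep(0L, nrow(grid))
           else as.integer(rowSums(grid[, seq_len(i), drop = FALSE]))
    mass <- vapply(0:i, function(a) sum(wts[age == a]), numeric(1))
    keep <- range(which(mass > 0))
    list(t_min = keep[1] - 1L, probs = mass[keep[1]:keep[2]] / sum(mass))
  })
}

# random but valid series: a mix of certain and uncertain boundaries with
# probabilities kept away from the trimming threshold's reach
random_test_series <- function(n_boundaries, seed, p_certain = 0.2,
                               widths = FALSE) {
  set.seed(seed)
  n <- n_boundaries - 1L
  p <- ifelse(stats::runif(n) < p_certain, 1, stats::runif(n, 0.3, 0.95))
  ring_series(
    c(1, p),
    width_cm = if (widths && n > 0) stats::runif(n, 0.01, 0.5) else NULL
  )
}

# the five-boundary worked example: two certain boundaries, two doubtful
# recognizable ones and one candidate missing boundary
worked_example_series <- function() {
  ring_series(c(1, 0.7, 1, 0.2, 0.9),
              type = c("base", "recognizable", "annual", "missing",
                       "recognizable"))
}

# the case-study structure: base boundary plus 48 at P = 0.83 (no widths)
case_study_series <- function() {
  ring_series(c(1, rep(0.83, 48)))
}

write_series_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
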