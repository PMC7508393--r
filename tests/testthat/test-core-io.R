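test_that("ring_series enforces the boundary invariants", {
  s <- ring_series(c(1, rep(0.83, 48)))
  expect_s3_class(s, "ring_series")
  expect_equal(n_boundaries(s), 49L)
  expect_equal(n_widths(s), 48L)

  # degenerate base-only series
  s0 <- ring_series(1)
  expect_equal(n_boundaries(s0), 1L)
  expect_equal(n_widths(s0), 0L)

  expect_error(ring_series(c(1, 1.2)), "outside")
  expect_error(ring_series(c(1, 0)), "outside")
  expect_error(ring_series(c(0.9, 0.5)), "probability 1")
  expect_error(ring_series(c(1, 0.5), type = c("recognizable", "recognizable")),
               "base")
  expect_error(ring_series(c(1, 0.5, 0.5), type = c("base", "base", "missing")),
               "boundary 0")
  expect_error(ring_series(c(1, 0.5), width_cm = c(0.1, 0.2)), "widths")
  expect_error(ring_series(c(1, 0.5), width_cm = -0.1), "non-negative")
  # zero widths allowed (overlapping boundaries / missing ring)
  expect_silent(ring_series(c(1, 0.5), width_cm = 0))
})

test_that("read_series parses the CSV dialect and validates it", {
  df <- data.frame(index = 0:48,
                   type = c("base", rep("recognizable", 48)),
                   probability = c(1, rep(0.83, 48)),
                   width_cm = c(NA, runif(48, 0.05, 0.4)))
  path <- write_series_csv(df)
  s <- read_series(path)
  expect_equal(n_boundaries(s), 49L)
  expect_equal(n_widths(s), 48L)
  expect_equal(boundary_probs(s), df$probability)

  # single-row base-only file
  p0 <- write_series_csv(df[1, ])
  expect_equal(n_boundaries(read_series(p0)), 1L)

  # rows shuffled on disk are reordered by index
  pshuf <- write_series_csv(df[sample(nrow(df)), ])
  expect_equal(as.data.frame(read_series(pshuf))$width_cm,
               c(NA, df$width_cm[-1]))

  # 'annual' is a synonym for recognizable; column synonyms accepted
  df2 <- data.frame(boundary = 0:2, type = c("base", "annual", "missing"),
                    p = c(1, 0.8, 0.4), width = c(NA, 0.1, 0.2))
  s2 <- read_series(write_series_csv(df2))
  expect_equal(s2$boundaries$type, c("base", "recognizable", "missing"))

  bad <- df; bad$probability[5] <- 1.2
  expect_error(read_series(write_series_csv(bad)), "outside")
  dup <- df; dup$index[3] <- 1L
  expect_error(read_series(write_series_csv(dup)), "duplicate|missing")
  gap <- df[-3, ]
  expect_error(read_series(write_series_csv(gap)), "missing boundary index 2")
  expect_error(read_series(tempfile()), "not found")
})

test_that("series round-trip through write_series preserves all fields", {
  s <- random_test_series(20, seed = 7, widths = TRUE)
  path <- tempfile(fileext = ".csv")
  write_series(s, path)
  back <- read_series(path, sample_id = s$sample_id)
  expect_equal(back$boundaries, s$boundaries, tolerance = 1e-12)
})

test_that("width_from_pixels applies the calibrated Euclidean length", {
  # digitized ring 3 of the case-study core: 19.1 px at 1738 px = 11.7 cm
  expect_equal(round(width_from_pixels(246, 178, 233, 164, 1738, 11.7), 3),
               0.129)
  expect_equal(width_from_pixels(0, 0, 0, 0, 100, 1), 0)
  expect_equal(width_from_pixels(0, 0, 3, 4, 10, 1), 0.5)

  # invariance under endpoint swap and rigid translation
  set.seed(1)
  for (k in 1:20) {
    xy <- rnorm(4, sd = 100); dx <- rnorm(1); dy <- rnorm(1)
    w1 <- width_from_pixels(xy[1], xy[2], xy[3], xy[4], 500, 3)
    expect_equal(width_from_pixels(xy[3], xy[4], xy[1], xy[2], 500, 3), w1)
    expect_equal(width_from_pixels(xy[1] + dx, xy[2] + dy,
                                   xy[3] + dx, xy[4] + dy, 500, 3), w1)
  }
  expect_error(width_from_pixels(0, 0, 1, 1, 0, 1), "positive")
  expect_error(width_from_pixels(0, 0, 1, 1, 10, 0), "positive")
})

test_that("pixel-segment files convert to widths in ring order", {
  seg <- data.frame(ring = c(2, 1), x1 = c(0, 0), y1 = c(0, 0),
                    x2 = c(0, 3), y2 = c(8, 4))
  path <- write_series_csv(seg)
  expect_equal(read_pixel_segments(path, scale_px = 10, scale_cm = 1),
               c(0.5, 0.8))
  bad <- write_series_csv(data.frame(ring = 1, x1 = 0))
  expect_error(read_pixel_segments(bad, 10, 1), "columns")
})

test_that("write_results round-trips summaries and stats in both formats", {
  s <- random_test_series(12, seed = 3, widths = TRUE)
  summ <- summarize_series(s)
  st <- series_stats(s)

  csv <- tempfile(fileext = ".csv")
  write_results(summ, st, csv, format = "csv")
  back <- read_results(csv, "csv")
  expect_equal(back$summaries$mean_age, round(summ$mean_age, 3))
  expect_equal(back$stats$ms, round(st$ms, 3))

  js <- tempfile(fileext = ".json")
  write_results(summ, st, js, format = "json", digits = 6)
  bj <- read_results(js, "json")
  expect_equal(bj$summaries$ci_upper, round(summ$ci_upper, 6))
  expect_equal(bj$stats$s_proc_prob, round(st$s_proc_prob, 6))
  # serialize/deserialize at high precision is a fixed point
  js2 <- tempfile(fileext = ".json")
  write_results(as.data.frame(bj$summaries), NULL, js2, format = "json",
                digits = 6)
  expect_equal(read_results(js2, "json")$summaries, bj$summaries)

  # empty summaries give a header-only table
  empty <- tempfile(fileext = ".csv")
  write_results(summ[0, ], NULL, empty, format = "csv")
  got <- read_results(empty, "csv")
  expect_equal(nrow(got$summaries), 0L)
  expect_equal(names(got$summaries), names(summ))
})
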