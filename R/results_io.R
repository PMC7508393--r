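#' Write dating results
#'
#' Writes the per-boundary age summary (one row per boundary: input
#' probability, possible-age range, mean age, standard deviation, confidence
#' limits) and, optionally, the series-statistics block.
#'
#' With `format = "csv"` the boundary table is written to `path` and the
#' statistics (if any) to a sibling file `<stem>_stats.csv` as `name,value`
#' rows, keeping the main table machine-readable. With `format = "json"` both
#' go into one JSON object with fields `summaries` and `stats`.
#'
#' @param summaries A [summarize_series()] table (may have zero rows).
#' @param stats Optional [series_stats()] result.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param digits Decimal places for rounding numeric output; default 3
#'   (matching the precision of the method's reference tables).
#' @return `path`, invisibly.
#' @export
write_results <- function(summaries, stats = NULL, path,
                          format = c("csv", "json"), digits = 3) {
  format <- match.arg(format)
  tab <- as.data.frame(summaries)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE, na = "")
    if (!is.null(stats)) {
      sdf <- data.frame(name = names(unclass(stats)),
                        value = round(unlist(unclass(stats)), digits))
      utils::write.csv(sdf, stats_path(path), row.names = FALSE)
    }
  } else {
    obj <- list(summaries = tab,
                stats = if (is.null(stats)) NULL else
                  lapply(unclass(stats), round, digits = digits))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

stats_path <- function(path) {
  sub("(\\.[A-Za-z0-9]+)?$", "_stats.csv", path)
}

#' Read back dating results
#'
#' Inverse of [write_results()]: returns the per-boundary table (and the
#' statistics, when present) at the written precision.
#'
#' @param path Path written by [write_results()].
#' @param format `"csv"` or `"json"`.
#' @return A list with `summaries` (data frame) and `stats` (named list or
#'   `NULL`).
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    summaries <- utils::read.csv(path)
    sp <- stats_path(path)
    stats <- if (file.exists(sp)) {
      s <- utils::read.csv(sp)
      as.list(stats::setNames(s$value, s$name))
    }
    list(summaries = summaries, stats = stats)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    list(summaries = as.data.frame(obj$summaries), stats = obj$stats)
  }
}
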