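#' Construct a ring series
#'
#' A `ring_series` is the unit of analysis: an ordered set of putative growth
#' boundaries along an increment core, numbered from 0 at the base boundary
#' (the innermost counted boundary, defined to have age 0 with certainty)
#' outwards to the cambium. Boundary `i` closes ring `i`, so a series with
#' `n_b` boundaries carries `n_w = n_b - 1` ring widths.
#'
#' Each boundary has a type (`"base"`, `"recognizable"` or `"missing"`) and an
#' input probability `p_annual` in (0, 1] that it is a true annual boundary
#' rather than a false (intra-annual) one. The base boundary is the only one
#' required to have probability 1; if even the starting point were doubtful,
#' ages relative to it would be meaningless.
#'
#' @param p_annual Numeric vector of input probabilities, one per boundary,
#'   starting with the base boundary (which must be 1). All values must lie in
#'   (0, 1].
#' @param width_cm Optional numeric vector of ring widths in cm, one per ring,
#'   i.e. of length `length(p_annual) - 1`; `width_cm[i]` is the width of the
#'   ring whose outer boundary is boundary `i`. Widths must be non-negative
#'   (a zero width represents a missing ring entered as two overlapping
#'   boundaries). `NULL` when no widths were measured.
#' @param type Optional character vector of boundary types; defaults to
#'   `"base"` for boundary 0 and `"recognizable"` elsewhere. The synonym
#'   `"annual"` is accepted for `"recognizable"`.
#' @param sample_id Free-text sample label.
#'
#' @return An object of class `ring_series`: a list with elements
#'   `sample_id` and `boundaries` (a data frame with columns `index`, `type`,
#'   `p_annual`, `width_cm`; `width_cm` is `NA` for the base boundary).
#' @examples
#' # the case-study structure: base boundary plus 48 boundaries at P = 0.83
#' s <- ring_series(c(1, rep(0.83, 48)))
#' n_boundaries(s)
#' @seealso [read_series()], [propagate()], [summarize_series()]
#' @export
ring_series <- function(p_annual, width_cm = NULL, type = NULL,
                        sample_id = "series") {
  p_annual <- as.numeric(p_annual)
  n_b <- length(p_annual)
  if (n_b < 1L) stop("a ring series needs at least the base boundary")
  if (is.null(type)) {
    type <- c("base", rep("recognizable", n_b - 1L))
  }
  type <- normalize_boundary_type(type)
  if (length(type) != n_b) {
    stop("'type' must have one entry per boundary")
  }
  if (is.null(width_cm)) {
    width_cm <- rep(NA_real_, max(n_b - 1L, 0L))
  }
  width_cm <- as.numeric(width_cm)
  if (length(width_cm) != n_b - 1L) {
    stop(sprintf("expected %d ring widths for %d boundaries, got %d",
                 n_b - 1L, n_b, length(width_cm)))
  }
  obj <- structure(
    list(
      sample_id = as.character(sample_id)[1],
      boundaries = data.frame(
        index = seq_len(n_b) - 1L,
        type = type,
        p_annual = p_annual,
        width_cm = c(NA_real_, width_cm),
        stringsAsFactors = FALSE
      )
    ),
    class = "ring_series"
  )
  validate_ring_series(obj)
}

normalize_boundary_type <- function(type) {
  type <- tolower(trimws(as.character(type)))
  type[type == "annual"] <- "recognizable"
  bad <- setdiff(unique(type), c("base", "recognizable", "missing"))
  if (length(bad)) {
    stop("unknown boundary type(s): ", paste(bad, collapse = ", "),
         " (expected base, annual, recognizable or missing)")
  }
  type
}

validate_ring_series <- function(x) {
  b <- x$boundaries
  n_b <- nrow(b)
  if (!identical(b$index, seq_len(n_b) - 1L)) {
    stop("boundary indices must be consecutive integers starting at 0")
  }
  if (b$type[1] != "base") {
    stop("boundary 0 must be the base boundary")
  }
  if (n_b > 1L && any(b$type[-1] == "base")) {
    stop("only boundary 0 may be of type 'base'")
  }
  if (b$p_annual[1] != 1) {
    stop("the base boundary must have input probability 1")
  }
  if (any(!is.finite(b$p_annual)) ||
      any(b$p_annual <= 0) || any(b$p_annual > 1)) {
    i <- which(!is.finite(b$p_annual) | b$p_annual <= 0 | b$p_annual > 1)[1]
    stop(sprintf("input probability at boundary %d is outside (0, 1]",
                 b$index[i]))
  }
  w <- b$width_cm[-1]
  if (length(w) && any(!is.na(w) & w < 0)) {
    stop("ring widths must be non-negative")
  }
  x
}

#' @export
print.ring_series <- function(x, ...) {
  b <- x$boundaries
  w <- ring_widths(x)
  cat(sprintf("Ring series '%s': %d boundaries (0..%d), %d ring widths\n",
              x$sample_id, nrow(b), nrow(b) - 1L, nrow(b) - 1L))
  cat(sprintf("  boundary types: %s\n",
              paste(sprintf("%s=%d", names(table(b$type)), table(b$type)),
                    collapse = ", ")))
  pr <- b$p_annual[-1]
  if (length(pr)) {
    cat(sprintf("  input probabilities: %s\n",
                if (length(unique(pr)) == 1L) format(pr[1])
                else sprintf("%.3g .. %.3g", min(pr), max(pr))))
  }
  if (length(w) && !anyNA(w)) {
    cat(sprintf("  total radius: %.4g cm\n", sum(w)))
  }
  invisible(x)
}

#' Accessors for ring series
#'
#' `n_boundaries()` and `n_widths()` return the number of boundaries `n_b` and
#' of ring widths `n_w = n_b - 1`; `boundary_probs()` returns the input
#' probabilities (including the base boundary's 1); `ring_widths()` the widths
#' in cm, ordered by ring number.
#'
#' @param x A `ring_series`.
#' @return An integer count or a numeric vector.
#' @export
n_boundaries <- function(x) nrow(x$boundaries)

#' @rdname n_boundaries
#' @export
n_widths <- function(x) nrow(x$boundaries) - 1L

#' @rdname n_boundaries
#' @export
boundary_probs <- function(x) x$boundaries$p_annual

#' @rdname n_boundaries
#' @export
ring_widths <- function(x) x$boundaries$width_cm[-1]

#' @export
as.data.frame.ring_series <- function(x, ...) x$boundaries

#' Read a ring-boundary table from CSV
#'
#' The expected dialect has a header row and columns `index`, `type`,
#' `probability`, `width_cm` (comma separated, dot decimal). Column-name
#' synonyms are accepted: `boundary` for `index`, `p`/`p_annual`/`prob` for
#' `probability`, `width` for `width_cm`. The `type` column accepts
#' base/annual/recognizable/missing. The width on a row is the width of the
#' ring whose outer boundary that row describes; the base row's width is
#' ignored (may be empty).
#'
#' @param path Path to a CSV file.
#' @param sample_id Sample label; defaults to the file name.
#' @return A validated [ring_series()].
#' @export
read_series <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, strip.white = TRUE, stringsAsFactors = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  pick <- function(cands, what) {
    hit <- intersect(cands, names(raw))
    if (!length(hit)) stop("no '", what, "' column in ", path)
    raw[[hit[1]]]
  }
  idx <- pick(c("index", "boundary", "boundary_number"), "index")
  typ <- pick(c("type", "boundary_type"), "type")
  prob <- pick(c("probability", "p_annual", "prob", "p"), "probability")
  wid <- raw[[intersect(c("width_cm", "width"), names(raw))[1]]]
  if (is.null(wid)) wid <- rep(NA_real_, nrow(raw))

  idx <- suppressWarnings(as.integer(idx))
  if (anyNA(idx)) {
    stop("non-integer boundary index at row ", which(is.na(idx))[1], " of ", path)
  }
  ord <- order(idx)
  idx <- idx[ord]; typ <- typ[ord]
  prob <- as.numeric(prob)[ord]
  wid <- as.numeric(wid)[ord]
  if (anyDuplicated(idx)) {
    stop("duplicate boundary index ", idx[anyDuplicated(idx)], " in ", path)
  }
  expect <- seq_len(length(idx)) - 1L
  if (!identical(idx, expect)) {
    stop("missing boundary index ", setdiff(expect, idx)[1], " in ", path)
  }
  ring_series(
    p_annual = prob,
    width_cm = if (length(idx) > 1L) wid[-1] else NULL,
    type = typ,
    sample_id = if (is.null(sample_id)) basename(path) else sample_id
  )
}

#' Write a ring series to CSV
#'
#' Emits the same dialect that [read_series()] reads
#' (`index,type,probability,width_cm`).
#'
#' @param x A `ring_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  b <- x$boundaries
  out <- data.frame(index = b$index, type = b$type,
                    probability = b$p_annual, width_cm = b$width_cm)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Ring width from pixel coordinates
#'
#' Widths digitized on a calibrated core image are segments between the inner
#' and outer boundary of a ring; the length is the Euclidean distance between
#' the endpoints, converted to cm with a pixels-per-cm calibration
#' (`scale_px` pixels correspond to `scale_cm` cm).
#'
#' @param x1,y1,x2,y2 Pixel coordinates of the segment endpoints (vectorized).
#' @param scale_px Pixels spanned by the calibration distance; must be > 0.
#' @param scale_cm Calibration distance in cm; must be > 0.
#' @return Width(s) in cm.
#' @examples
#' width_from_pixels(246, 178, 233, 164, scale_px = 1738, scale_cm = 11.7)
#' @export
width_from_pixels <- function(x1, y1, x2, y2, scale_px, scale_cm) {
  if (!is.finite(scale_px) || scale_px <= 0) {
    stop("'scale_px' must be a positive number of pixels")
  }
  if (!is.finite(scale_cm) || scale_cm <= 0) {
    stop("'scale_cm' must be a positive length in cm")
  }
  sqrt((x2 - x1)^2 + (y2 - y1)^2) * scale_cm / scale_px
}

#' Read digitized width segments
#'
#' Reads a CSV of pixel segments (`ring,x1,y1,x2,y2`) and converts each to a
#' width in cm via [width_from_pixels()]. Rows are ordered by ring number.
#'
#' @param path CSV path.
#' @inheritParams width_from_pixels
#' @return Numeric vector of widths in cm, one per ring.
#' @export
read_pixel_segments <- function(path, scale_px, scale_cm) {
  seg <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(seg) <- tolower(names(seg))
  need <- c("ring", "x1", "y1", "x2", "y2")
  if (!all(need %in% names(seg))) {
    stop("pixel-segment file must have columns ", paste(need, collapse = ","))
  }
  seg <- seg[order(seg$ring), ]
  width_from_pixels(seg$x1, seg$y1, seg$x2, seg$y2, scale_px, scale_cm)
}
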