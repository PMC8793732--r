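# Serial-variation metrics over articular-facet aspect ratios.
#
# Both metrics act on the V/H series (vertical extent / horizontal extent per
# facet, computed at full precision from the raw measurements, never from
# display-rounded values):
#   metric_diff_x100  = mean |vh[i] - vh[i+1]|            * 100
#   metric_ratio_x100 = (mean max(r, 1/r) - 1) * 100,  r = vh[i]/vh[i+1]
# Undistorted necks vary smoothly, so both are small; uncorrelated
# per-vertebra crushing inflates both.

#' Aspect ratio of an articular facet
#'
#' V/H: vertical extent over horizontal extent. Values below 1 mean the facet
#' is wider than tall; the ratio is independent of measurement units.
#'
#' @param vertical,horizontal positive facet extents in a common unit.
#' @return `vertical / horizontal`. Vectorized.
#' @examples
#' aspect_ratio(437, 638)  # giraffe C2, wider than tall
#' @export
aspect_ratio <- function(vertical, horizontal) {
  if (any(!is.finite(vertical)) || any(!is.finite(horizontal)) ||
      any(vertical <= 0) || any(horizontal <= 0))
    stop("aspect_ratio: extents must be positive and finite")
  vertical / horizontal
}

#' Aspect-ratio series of a column
#'
#' @param series a [column_series].
#' @return Object of class `aspect_ratio_series`: list with `specimen_id`,
#'   `labels` (element labels) and `vh` (per-vertebra V/H ratios, order
#'   preserved).
#' @export
series_ratios <- function(series) {
  stopifnot(inherits(series, "column_series"))
  vh <- tryCatch(aspect_ratio(series$vertical, series$horizontal),
                 error = function(e) {
                   bad <- series$vertical <= 0 | series$horizontal <= 0
                   stop("invalid extents at element(s) ",
                        paste(series$element_label[bad], collapse = ", "))
                 })
  structure(list(specimen_id = attr(series, "specimen_id"),
                 labels = series$element_label, vh = vh),
            class = "aspect_ratio_series")
}

#' @export
print.aspect_ratio_series <- function(x, digits = 3, ...) {
  cat(sprintf("V/H aspect ratios, %s:\n", x$specimen_id))
  print(stats::setNames(round(x$vh, digits), x$labels))
  invisible(x)
}

as_vh <- function(x) {
  if (inherits(x, "column_series")) x <- series_ratios(x)
  if (inherits(x, "aspect_ratio_series")) x <- x$vh
  vh <- as.numeric(x)
  if (any(!is.finite(vh)) || any(vh <= 0)) stop("V/H values must be positive")
  if (length(vh) < 2L)
    stop("insufficient data: at least 2 vertebrae are required")
  vh
}

#' Absolute first differences of consecutive aspect ratios
#'
#' Entry i is `|vh[i] - vh[i+1]|`, the shape change from each vertebra to its
#' successor.
#'
#' @param ratios an `aspect_ratio_series`, a [column_series], or a numeric
#'   V/H vector of length >= 2.
#' @return Numeric vector of length n-1.
#' @export
consecutive_diffs <- function(ratios) {
  abs(diff(as_vh(ratios)))
}

#' Normalized first ratios of consecutive aspect ratios
#'
#' Entry i is `max(r, 1/r)` with `r = vh[i]/vh[i+1]`: the "absolute ratio",
#' normalized to be >= 1 so that widening and narrowing count alike.
#'
#' @inheritParams consecutive_diffs
#' @return Numeric vector of length n-1, every entry >= 1.
#' @export
consecutive_abs_ratios <- function(ratios) {
  vh <- as_vh(ratios)
  r <- vh[-length(vh)] / vh[-1L]
  pmax(r, 1 / r)
}

#' Serial-variation summary of a column series
#'
#' Computes the full serial-variation summary for one specimen: per-pair
#' absolute differences and normalized ratios of consecutive V/H aspect
#' ratios, their maxima and means, and the two headline metrics
#' `metric_diff_x100 = mean(diffs) * 100` and
#' `metric_ratio_x100 = (mean(ratios) - 1) * 100`. All quantities are
#' computed from the raw extents at full precision.
#'
#' @param series a [column_series] with at least 2 measurements.
#' @param gap_policy `"span"` (default) treats the next preserved vertebra as
#'   the successor even across a gap in `serial_index`; `"strict"` raises an
#'   error naming the missing positions.
#' @return Object of class `serial_variation` with fields `specimen_id`,
#'   `taxon`, `n`, `labels`, `vh`, `first_diffs`, `max_diff`, `avg_diff`,
#'   `metric_diff_x100`, `first_ratios`, `max_ratio`, `avg_ratio`,
#'   `metric_ratio_x100`.
#' @examples
#' sv <- serial_variation(load_fixture("diplodocus_cm84"))
#' sv$metric_diff_x100   # about 9.13
#' summary(sv)
#' @export
serial_variation <- function(series, gap_policy = c("span", "strict")) {
  stopifnot(inherits(series, "column_series"))
  gap_policy <- match.arg(gap_policy)
  if (nrow(series) < 2L)
    stop("insufficient data: at least 2 vertebrae are required")
  if (gap_policy == "strict") {
    steps <- diff(series$serial_index)
    if (any(steps != 1L)) {
      missing_idx <- unlist(lapply(which(steps != 1L), function(i)
        seq(series$serial_index[i] + 1L, series$serial_index[i + 1L] - 1L)))
      stop(sprintf("specimen '%s': serial gap, missing serial index(es) %s",
                   attr(series, "specimen_id"),
                   paste(missing_idx, collapse = ", ")))
    }
  }
  ar <- series_ratios(series)
  d <- consecutive_diffs(ar)
  r <- consecutive_abs_ratios(ar)
  structure(list(specimen_id = attr(series, "specimen_id"),
                 taxon = attr(series, "taxon"),
                 n = nrow(series),
                 labels = series$element_label,
                 vh = ar$vh,
                 first_diffs = d,
                 max_diff = max(d),
                 avg_diff = mean(d),
                 metric_diff_x100 = mean(d) * 100,
                 first_ratios = r,
                 max_ratio = max(r),
                 avg_ratio = mean(r),
                 metric_ratio_x100 = (mean(r) - 1) * 100),
            class = "serial_variation")
}

#' @export
print.serial_variation <- function(x, digits = 3, ...) {
  cat(sprintf("Serial variation: %s (%s), %d vertebrae %s-%s\n",
              x$specimen_id, x$taxon, x$n,
              x$labels[1L], x$labels[x$n]))
  cat(sprintf("  mean |1st diff| x100 : %s\n", fmt_fixed(x$metric_diff_x100, digits)))
  cat(sprintf("  (mean 1st ratio - 1) x100 : %s\n", fmt_fixed(x$metric_ratio_x100, digits)))
  cat(sprintf("  max diff %s, max ratio %s\n",
              fmt_fixed(x$max_diff, digits), fmt_fixed(x$max_ratio, digits)))
  invisible(x)
}

#' @export
summary.serial_variation <- function(object, digits = 3, ...) {
  x <- object
  per_pair <- data.frame(
    pair = paste(x$labels[-x$n], x$labels[-1L], sep = "-"),
    first_diff = round(x$first_diffs, digits),
    first_ratio = round(x$first_ratios, digits))
  out <- list(per_pair = per_pair, totals = as.data.frame(x, digits = digits))
  class(out) <- "summary.serial_variation"
  out
}

#' @export
print.summary.serial_variation <- function(x, ...) {
  print(x$totals, row.names = FALSE)
  cat("\nPer consecutive pair:\n")
  print(x$per_pair, row.names = FALSE)
  invisible(x)
}

#' @param digits rounding for report columns (`NULL` for full precision);
#'   round-half-even, mirroring the published table's 3-dp convention.
#' @rdname serial_variation
#' @export
as.data.frame.serial_variation <- function(x, ..., digits = NULL) {
  d <- data.frame(specimen_id = x$specimen_id, taxon = x$taxon, n = x$n,
                  max_diff = x$max_diff, avg_diff = x$avg_diff,
                  metric_diff_x100 = x$metric_diff_x100,
                  max_ratio = x$max_ratio, avg_ratio = x$avg_ratio,
                  metric_ratio_x100 = x$metric_ratio_x100,
                  stringsAsFactors = FALSE)
  if (!is.null(digits)) {
    num <- vapply(d, is.numeric, logical(1)) & names(d) != "n"
    d[num] <- lapply(d[num], round, digits = digits)
  }
  d
}

fmt_fixed <- function(x, digits) formatC(round(x, digits), format = "f", digits = digits)
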