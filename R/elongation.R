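# Elongation indices and pairwise distortion comparisons.
#
# EI  = centrum length / cotyle height.
# aEI = centrum length / mean(cotyle height, cotyle width); partially robust
#       to dorsoventral crushing, but oblique crushing can inflate both
#       extents and so still bias it.
# The crush correction rescales an observed cotyle width by the V/H ratio of
# a reference facet the worker judges undistorted, giving the height the
# cotyle would have had under the reference proportions.

check_positive <- function(..., what = "input") {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop(what, " must be positive and finite")
  invisible(vals)
}

#' Elongation index (EI)
#'
#' Centrum length divided by cotyle height, the elongation measure widely
#' used as a phylogenetic character for sauropod cervicals.
#'
#' @param centrum_length,cotyle_height positive lengths in a common unit.
#' @return `centrum_length / cotyle_height`. Vectorized.
#' @examples
#' elongation_index(45.7, 13.8)  # about 3.31
#' @export
elongation_index <- function(centrum_length, cotyle_height) {
  check_positive(centrum_length, cotyle_height, what = "lengths")
  centrum_length / cotyle_height
}

#' Average elongation index (aEI)
#'
#' Centrum length divided by the mean of cotyle height and width. Averaging
#' the two extents partially cancels uniaxial crushing, though oblique
#' area-preserving crushing can still depress it.
#'
#' @param centrum_length,cotyle_height,cotyle_width positive lengths in a
#'   common unit.
#' @return `centrum_length / ((cotyle_height + cotyle_width) / 2)`.
#' @examples
#' average_elongation_index(10, 2, 2)  # equals EI when height == width
#' @export
average_elongation_index <- function(centrum_length, cotyle_height, cotyle_width) {
  check_positive(centrum_length, cotyle_height, cotyle_width, what = "lengths")
  centrum_length / ((cotyle_height + cotyle_width) / 2)
}

#' Crush-corrected cotyle height
#'
#' Estimates the true cotyle height of a crushed vertebra under the
#' assumption that its undistorted proportions matched those of a reference
#' facet: the observed width is rescaled by the reference V/H ratio.
#'
#' @param observed_width observed cotyle width of the crushed vertebra.
#' @param reference_vh V/H (height/width) aspect ratio of the undistorted
#'   reference facet, supplied by the caller (reference choice is a
#'   judgement, not automated).
#' @return `observed_width * reference_vh`.
#' @examples
#' # C6 cotyle width 22.1 cm, rescaled by the C4 V/H ratio 672/644:
#' corrected_cotyle_height(22.1, aspect_ratio(672, 644))  # about 23.1 cm
#' @export
corrected_cotyle_height <- function(observed_width, reference_vh) {
  check_positive(observed_width, reference_vh)
  observed_width * reference_vh
}

#' Factor by which two aspect ratios differ
#'
#' Order-free comparison of two facet aspect ratios expressed in the same
#' orientation convention: `max(a/b, b/a)`, always >= 1.
#'
#' @param ratio_a,ratio_b positive aspect ratios.
#' @return The multiplicative factor separating the two ratios.
#' @examples
#' aspect_ratio_factor(1190 / 820, 683 / 722)  # about 1.53
#' @export
aspect_ratio_factor <- function(ratio_a, ratio_b) {
  check_positive(ratio_a, ratio_b, what = "ratios")
  pmax(ratio_a / ratio_b, ratio_b / ratio_a)
}

#' Percentage by which one facet is broader than another
#'
#' Takes width:height (W/H) ratios — the convention of measurements made on
#' published photographs — and returns how much broader, proportionally, the
#' first facet is than the second. Negative values mean narrower. Note
#' W/H = 1 / (V/H).
#'
#' @param wh_a,wh_b positive width:height ratios.
#' @return `(wh_a / wh_b - 1) * 100`.
#' @examples
#' percent_broader(342 / 245, 264 / 256)  # about 35
#' @export
percent_broader <- function(wh_a, wh_b) {
  check_positive(wh_a, wh_b, what = "ratios")
  (wh_a / wh_b - 1) * 100
}

#' Elongation report for a set of vertebrae
#'
#' Convenience tabulation: EI, aEI (where width is available), and optionally
#' a crush-corrected height and EI against a caller-chosen reference element.
#'
#' @param elements data.frame with columns `element_label`, `centrum_length`,
#'   `cotyle_height`, and optionally `cotyle_width`.
#' @param reference_element label of the row whose V/H
#'   (`cotyle_height / cotyle_width`) supplies the correction ratio, or
#'   `NULL` to skip correction.
#' @return data.frame with columns `element_label`, `centrum_length`,
#'   `cotyle_height`, `cotyle_width`, `EI`, `aEI`, `corrected_height`,
#'   `corrected_EI`, `reference_element`.
#' @export
elongation_report <- function(elements, reference_element = NULL) {
  e <- as.data.frame(elements)
  stopifnot(all(c("element_label", "centrum_length", "cotyle_height") %in% names(e)))
  if (is.null(e$cotyle_width)) e$cotyle_width <- NA_real_
  out <- data.frame(element_label = e$element_label,
                    centrum_length = e$centrum_length,
                    cotyle_height = e$cotyle_height,
                    cotyle_width = e$cotyle_width,
                    EI = elongation_index(e$centrum_length, e$cotyle_height),
                    aEI = NA_real_, corrected_height = NA_real_,
                    corrected_EI = NA_real_,
                    reference_element = NA_character_,
                    stringsAsFactors = FALSE)
  has_w <- !is.na(e$cotyle_width)
  out$aEI[has_w] <- average_elongation_index(e$centrum_length[has_w],
                                             e$cotyle_height[has_w],
                                             e$cotyle_width[has_w])
  if (!is.null(reference_element)) {
    ref <- match(reference_element, e$element_label)
    if (is.na(ref)) stop("reference element '", reference_element, "' not in table")
    if (is.na(e$cotyle_width[ref]))
      stop("reference element '", reference_element, "' has no cotyle_width")
    ref_vh <- e$cotyle_height[ref] / e$cotyle_width[ref]
    out$corrected_height[has_w] <-
      corrected_cotyle_height(e$cotyle_width[has_w], ref_vh)
    out$corrected_EI[has_w] <-
      elongation_index(e$centrum_length[has_w], out$corrected_height[has_w])
    out$reference_element <- reference_element
  }
  out
}
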