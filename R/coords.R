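#' Convert genomic intervals between 1-based closed and 0-based half-open
#'
#' Variant loci are kept 1-based (the VCF convention) and gene intervals
#' 0-based half-open (the BED convention); these two functions are the single
#' conversion point between the conventions. They are exact inverses of each
#' other for any valid interval.
#'
#' @param start,end Interval bounds. For `interval_to_zero_based()` they are
#'   1-based closed (GFF3 style, `start <= end`); for
#'   `interval_to_one_based()` they are 0-based half-open (`start < end`).
#' @return A two-column data frame with converted `start` and `end`.
#' @examples
#' interval_to_zero_based(101, 200)   # -> (100, 200)
#' interval_to_one_based(100, 200)    # -> (101, 200)
#' @export
interval_to_zero_based <- function(start, end) {
  if (any(start < 1) || any(end < start)) {
    stop_input("invalid 1-based closed interval: need 1 <= start <= end")
  }
  data.frame(start = start - 1L, end = end)
}

#' @rdname interval_to_zero_based
#' @export
interval_to_one_based <- function(start, end) {
  if (any(start < 0) || any(end <= start)) {
    stop_input("invalid 0-based half-open interval: need 0 <= start < end")
  }
  data.frame(start = start + 1L, end = end)
}
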