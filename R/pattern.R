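#' Create an ASRT pattern sequence
#'
#' An ASRT pattern sequence is a permutation of the four screen positions
#' that the pattern elements cycle through. In the eight-element task
#' sequence (e.g. `2 - r - 4 - r - 3 - r - 1 - r`) the numbered elements are
#' the pattern positions and `r` marks a uniformly random element, so the
#' pattern induces second-order dependencies: position `n - 2` predicts
#' position `n`.
#'
#' @param order Integer vector of length 4: a permutation of `1:4`, the
#'   pattern positions read left to right.
#' @param label Sequence identity tag, conventionally `"A"` for the trained
#'   sequence and `"B"` for its reversal.
#'
#' @return An object of class `asrt_pattern`.
#' @examples
#' a <- asrt_pattern(c(2, 4, 3, 1))
#' successor_map(a)
#' reverse_pattern(a)
#' @export
asrt_pattern <- function(order, label = "A") {
  order <- as.integer(order)
  if (length(order) != 4L || anyNA(order) || !setequal(order, 1:4)) {
    abort("`order` must be a permutation of positions 1:4.",
          class = "asrt_invalid_design")
  }
  label <- as.character(label)[1]
  structure(list(order = order, label = label), class = "asrt_pattern")
}

#' @export
print.asrt_pattern <- function(x, ...) {
  cat("<asrt_pattern ", x$label, "> ",
      paste(x$order, collapse = " - r - "), " - r\n", sep = "")
  invisible(x)
}

is_asrt_pattern <- function(x) inherits(x, "asrt_pattern")

#' Cyclic successor map of a pattern sequence
#'
#' Returns the next-element map induced by the pattern cycle. For pattern
#' `(2, 4, 3, 1)` the map is `2 -> 4, 4 -> 3, 3 -> 1, 1 -> 2`; a trial at
#' position `succ(p)` two steps after a trial at position `p` ends a
#' high-probability triplet.
#'
#' @param pattern An [asrt_pattern()].
#' @return Integer vector of length 4; element `p` is the successor of
#'   position `p`. Because `order` is a single 4-cycle, the map has no fixed
#'   points and no 2-cycles.
#' @export
successor_map <- function(pattern) {
  if (!is_asrt_pattern(pattern)) pattern <- asrt_pattern(pattern)
  ord <- pattern$order
  succ <- integer(4)
  succ[ord] <- ord[c(2:4, 1L)]
  succ
}

#' Reverse a pattern sequence
#'
#' The interference manipulation replaces the trained sequence A by its
#' reversal B (e.g. A `2-r-4-r-3-r-1-r`, B `1-r-3-r-4-r-2-r`). The successor
#' map of the reversal equals the predecessor map of the original, which is
#' what makes `H H` triplets (high-probability under both) impossible.
#'
#' @param pattern An [asrt_pattern()].
#' @param label Label for the reversed sequence; by default `"B"` if the
#'   input is labelled `"A"` and `"A"` otherwise.
#' @return An `asrt_pattern` with the order reversed.
#' @export
reverse_pattern <- function(pattern, label = NULL) {
  if (!is_asrt_pattern(pattern)) pattern <- asrt_pattern(pattern)
  if (is.null(label)) label <- if (identical(pattern$label, "A")) "B" else "A"
  asrt_pattern(rev(pattern$order), label = label)
}
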