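#' Extended 4x4 confusion matrix from a gated matching
#'
#' Tallies the correspondence between two cell sets over the three cell
#' classes plus a virtual `missing` class: a matched pair increments the
#' `(left label, right label)` entry, a cell unmatched on the left
#' increments `(label, missing)`, and a cell unmatched on the right
#' increments `(missing, label)`. The `(missing, missing)` entry is zero by
#' construction: a cell absent from both sets does not exist.
#'
#' @param left,right The cell sets the match was produced from.
#' @param match A [match_sets()] result for `(left, right)`.
#' @return An `extended_confusion` object: a 4x4 integer matrix with
#'   dimnames over `c(cell_labels(), "missing")` and attributes
#'   `left_source` / `right_source`.
#' @export
#' @examples
#' a <- cell_set("r", "A", c(0, 100), c(0, 100), label = c("tumor", "cd3_positive"))
#' b <- cell_set("r", "B", 0, 0, label = "tumor")
#' confusion_from_match(a, b, match_sets(a, b))
confusion_from_match <- function(left, right, match) {
  left <- as_cell_set(left, allow_diverse = TRUE)
  right <- as_cell_set(right, allow_diverse = TRUE)
  idx <- c(match$pairs$left, match$unmatched_left)
  jdx <- c(match$pairs$right, match$unmatched_right)
  if (length(idx) > 0 && max(idx) > nrow(left) ||
      length(jdx) > 0 && max(jdx) > nrow(right)) {
    stop("match indices out of range for the supplied sets", call. = FALSE)
  }
  lv <- cell_labels(missing = TRUE)
  ll <- factor(c(left$label[match$pairs$left], left$label[match$unmatched_left],
                 rep("missing", length(match$unmatched_right))), levels = lv)
  rl <- factor(c(right$label[match$pairs$right],
                 rep("missing", length(match$unmatched_left)),
                 right$label[match$unmatched_right]), levels = lv)
  if (anyNA(ll) || anyNA(rl)) {
    stop("diverse-labeled cells cannot enter a confusion matrix; ",
         "drop them before matching", call. = FALSE)
  }
  counts <- unclass(table(left = ll, right = rl))
  new_extended_confusion(counts,
                         left_source = source_of(left),
                         right_source = source_of(right))
}

source_of <- function(cells) {
  if (nrow(cells) == 0) NA_character_ else cells$source_id[1]
}

new_extended_confusion <- function(counts, left_source = NA_character_,
                                   right_source = NA_character_) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  lv <- cell_labels(missing = TRUE)
  stopifnot(identical(dim(counts), c(4L, 4L)))
  dimnames(counts) <- list(left = lv, right = lv)
  if (counts["missing", "missing"] != 0) {
    stop("counts[missing, missing] must be zero", call. = FALSE)
  }
  structure(counts, class = c("extended_confusion", "matrix", "array"),
            left_source = left_source, right_source = right_source)
}

#' Build an extended confusion matrix from raw counts
#'
#' Convenience constructor for a 4x4 count matrix ordered
#' `tumor, cd3_positive, non_specified, missing` on both axes (rows = left
#' rater, columns = right rater). The `(missing, missing)` entry must be 0.
#'
#' @param counts 4x4 non-negative integer matrix.
#' @param left_source,right_source Optional source identifiers.
#' @return An `extended_confusion` object.
#' @export
extended_confusion <- function(counts, left_source = NA_character_,
                               right_source = NA_character_) {
  if (any(counts < 0)) stop("confusion counts must be non-negative", call. = FALSE)
  new_extended_confusion(counts, left_source, right_source)
}

#' @export
print.extended_confusion <- function(x, ...) {
  cat("<extended_confusion>",
      attr(x, "left_source"), "(rows) vs", attr(x, "right_source"), "(cols)\n")
  print(unclass(x))
  invisible(x)
}

#' @export
tidy.extended_confusion <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame.table(unclass(x), stringsAsFactors = FALSE))
  names(out) <- c("left_label", "right_label", "n")
  out
}

# transpose keeps class/attrs swapped
#' @export
t.extended_confusion <- function(x) {
  new_extended_confusion(t(unclass(x)),
                         left_source = attr(x, "right_source"),
                         right_source = attr(x, "left_source"))
}
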