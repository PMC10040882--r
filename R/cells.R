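#' Canonical cell class labels
#'
#' The three biological classes used throughout the package, optionally
#' extended with the consensus-only `"diverse"` tie class and the virtual
#' `"missing"` class used in extended confusion matrices.
#'
#' @param diverse Include the `"diverse"` consensus label.
#' @param missing Include the `"missing"` pseudo-class (confusion matrices
#'   only; never a valid label on a cell record).
#' @return Character vector of label strings.
#' @export
#' @examples
#' cell_labels()
#' cell_labels(diverse = TRUE)
cell_labels <- function(diverse = FALSE, missing = FALSE) {
  out <- c("tumor", "cd3_positive", "non_specified")
  if (diverse) out <- c(out, "diverse")
  if (missing) out <- c(out, "missing")
  out
}

cell_set_cols <- c(
  "roi_id", "source_id", "center_x", "center_y",
  "min_x", "min_y", "max_x", "max_y", "label", "score"
)

#' Construct a cell annotation/detection set
#'
#' A cell set is an ordinary tibble with one row per cell and the columns
#' `roi_id`, `source_id`, `center_x`, `center_y`, `min_x`, `min_y`, `max_x`,
#' `max_y`, `label` and `score`. Box columns and `score` may be `NA`
#' (annotations carry no score; point annotations may carry no box). All
#' package functions accept and return these tibbles so pipelines compose
#' with the pipe.
#'
#' Coordinates are 0-based pixels, origin at the top-left corner, x growing
#' rightward and y downward; boxes are closed intervals.
#'
#' @param roi_id,source_id Character identifiers of the region of interest
#'   and of the annotation source (rater, software, detector, consensus).
#' @param center_x,center_y Numeric cell-center coordinates in pixels.
#' @param min_x,min_y,max_x,max_y Optional bounding-box vertices in pixels.
#' @param label Character labels; see [cell_labels()].
#' @param score Optional detection scores in `[0, 1]`.
#' @param allow_diverse Permit the consensus-only `"diverse"` label.
#' @return A validated cell-set tibble.
#' @export
#' @examples
#' cell_set(
#'   roi_id = "roi1", source_id = "raterA",
#'   center_x = c(10, 40), center_y = c(10, 40),
#'   label = c("tumor", "cd3_positive")
#' )
cell_set <- function(roi_id = character(), source_id = character(),
                     center_x = numeric(), center_y = numeric(),
                     min_x = NA_real_, min_y = NA_real_,
                     max_x = NA_real_, max_y = NA_real_,
                     label = character(), score = NA_real_,
                     allow_diverse = FALSE) {
  n <- length(center_x)
  cells <- tibble::tibble(
    roi_id = rep_len(as.character(roi_id), n),
    source_id = rep_len(as.character(source_id), n),
    center_x = as.numeric(center_x),
    center_y = as.numeric(center_y),
    min_x = rep_len(as.numeric(min_x), n),
    min_y = rep_len(as.numeric(min_y), n),
    max_x = rep_len(as.numeric(max_x), n),
    max_y = rep_len(as.numeric(max_y), n),
    label = rep_len(as.character(label), n),
    score = rep_len(as.numeric(score), n)
  )
  validate_cell_set(cells, allow_diverse = allow_diverse)
}

#' Coerce a data frame to a cell set
#'
#' Fills absent optional columns (`min_x` ... `max_x`, `score`) with `NA` and
#' validates invariants: finite non-negative centers, known labels, box
#' consistency (`min < max`, center within 0.5 px of the box centroid) and
#' scores in `[0, 1]`.
#'
#' @param x A data frame with at least `roi_id`, `source_id`, `center_x`,
#'   `center_y`, `label`.
#' @param allow_diverse Permit the consensus-only `"diverse"` label.
#' @return A validated cell-set tibble.
#' @export
as_cell_set <- function(x, allow_diverse = FALSE) {
  x <- tibble::as_tibble(x)
  need <- c("roi_id", "source_id", "center_x", "center_y", "label")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("cell set is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("min_x", "min_y", "max_x", "max_y", "score")) {
    if (!col %in% names(x)) x[[col]] <- NA_real_
  }
  x <- dplyr::mutate(
    x,
    dplyr::across(dplyr::all_of(c("roi_id", "source_id", "label")), as.character),
    dplyr::across(dplyr::all_of(setdiff(cell_set_cols, c("roi_id", "source_id", "label"))), as.numeric)
  )
  validate_cell_set(dplyr::select(x, dplyr::all_of(cell_set_cols)),
                    allow_diverse = allow_diverse)
}

validate_cell_set <- function(cells, allow_diverse = FALSE) {
  ok_labels <- cell_labels(diverse = allow_diverse)
  bad <- which(!cells$label %in% ok_labels)
  if (length(bad) > 0) {
    stop("unknown label '", cells$label[bad[1]], "' in row ", bad[1],
         " (expected one of: ", paste(ok_labels, collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(!is.finite(cells$center_x)) || any(!is.finite(cells$center_y))) {
    stop("non-numeric or missing cell center coordinate", call. = FALSE)
  }
  if (any(cells$center_x < 0) || any(cells$center_y < 0)) {
    stop("cell centers must be non-negative pixel coordinates", call. = FALSE)
  }
  has_box <- !is.na(cells$min_x)
  if (any(has_box)) {
    b <- cells[has_box, ]
    if (any(is.na(b$min_y) | is.na(b$max_x) | is.na(b$max_y))) {
      stop("incomplete bounding box: all four vertices are required", call. = FALSE)
    }
    if (any(b$min_x >= b$max_x) || any(b$min_y >= b$max_y)) {
      stop("degenerate bounding box: min vertex must be below max vertex",
           call. = FALSE)
    }
    cx <- (b$min_x + b$max_x) / 2
    cy <- (b$min_y + b$max_y) / 2
    if (any(abs(cx - b$center_x) > 0.5) || any(abs(cy - b$center_y) > 0.5)) {
      stop("cell center must equal the box centroid to within 0.5 px",
           call. = FALSE)
    }
  }
  has_score <- !is.na(cells$score)
  if (any(cells$score[has_score] < 0 | cells$score[has_score] > 1)) {
    stop("detection scores must lie in [0, 1]", call. = FALSE)
  }
  cells
}

# Split a combined tibble (or pass through a list) into one cell set per
# source_id, named by source. Used by consensus/agreement entry points.
split_sources <- function(sets) {
  if (is.data.frame(sets)) {
    sets <- as_cell_set(sets, allow_diverse = TRUE)
    out <- split(sets, sets$source_id)
  } else {
    out <- lapply(sets, as_cell_set, allow_diverse = TRUE)
    nm <- vapply(out, function(s) {
      if (nrow(s) == 0) return(NA_character_)
      s$source_id[1]
    }, character(1))
    # empty sets carry no source id; name them by position
    nm[is.na(nm)] <- paste0("set", which(is.na(nm)))
    names(out) <- nm
  }
  if (anyDuplicated(names(out)) > 0) {
    stop("duplicate source_ids across input sets", call. = FALSE)
  }
  out
}

stop_if_mixed_roi <- function(sets) {
  rois <- unique(unlist(lapply(sets, function(s) unique(s$roi_id))))
  if (length(rois) > 1) {
    stop("sets span multiple roi_ids (", paste(rois, collapse = ", "),
         "); evaluate one ROI at a time or pool explicitly", call. = FALSE)
  }
  invisible(rois)
}

# Synthesize a square box of the given side around each center (point
# annotations). Side 50 px means center +/- 25 px.
add_point_boxes <- function(cells, side = 50) {
  half <- side / 2
  dplyr::mutate(
    cells,
    min_x = .data$center_x - half, min_y = .data$center_y - half,
    max_x = .data$center_x + half, max_y = .data$center_y + half
  )
}
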