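#' Read a cell annotation or detection CSV
#'
#' Two dialects are supported. The `box` dialect carries bounding-box
#' vertices (columns `roi_id, source_id, min_x, min_y, max_x, max_y, label,
#' score`; `score` blank for plain annotations). The `point` dialect carries
#' one-click cell centers (`roi_id, source_id, center_x, center_y, label`);
#' a square box of side `point_box_side` pixels is synthesized around each
#' center, mirroring the convention of drawing a fixed-size box (about one
#' average cell) around a clicked center.
#'
#' Files are UTF-8, comma-separated, `.` decimal, header mandatory. Labels
#' are matched case-insensitively and written back in canonical lowercase.
#'
#' @param path Path to the CSV file.
#' @param dialect `"box"` or `"point"`.
#' @param point_box_side Side length (pixels) of the synthesized square box
#'   in the point dialect. Default 50 px, i.e. center +/- 25 px (the radius
#'   of an average cell at 0.23 um/px).
#' @param allow_diverse Accept the consensus-only `"diverse"` label.
#' @return A cell-set tibble ([cell_set()]), row order preserved.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "roi_id,source_id,min_x,min_y,max_x,max_y,label,score",
#'   "roi1,sw,0,0,20,20,tumor,",
#'   "roi1,sw,30,30,56,56,cd3_positive,"
#' ), f)
#' read_annotation_csv(f)
read_annotation_csv <- function(path, dialect = c("box", "point"),
                                point_box_side = 50, allow_diverse = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- if (dialect == "box") {
    c("roi_id", "source_id", "min_x", "min_y", "max_x", "max_y", "label")
  } else {
    c("roi_id", "source_id", "center_x", "center_y", "label")
  }
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("CSV is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  num_col <- function(col) {
    v <- raw[[col]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(out))
    if (length(bad) > 0) {
      stop("non-numeric value '", v[bad[1]], "' in column '", col,
           "', row ", bad[1], call. = FALSE)
    }
    out
  }

  label <- tolower(trimws(raw$label))
  ok <- cell_labels(diverse = allow_diverse)
  bad <- which(!label %in% ok)
  if (length(bad) > 0) {
    stop("unknown label '", raw$label[bad[1]], "' in row ", bad[1],
         call. = FALSE)
  }

  if (dialect == "box") {
    min_x <- num_col("min_x"); min_y <- num_col("min_y")
    max_x <- num_col("max_x"); max_y <- num_col("max_y")
    score <- if ("score" %in% names(raw)) num_col("score") else NA_real_
    cells <- tibble::tibble(
      roi_id = raw$roi_id, source_id = raw$source_id,
      center_x = (min_x + max_x) / 2, center_y = (min_y + max_y) / 2,
      min_x = min_x, min_y = min_y, max_x = max_x, max_y = max_y,
      label = label,
      score = rep_len(score, nrow(raw))
    )
  } else {
    cells <- tibble::tibble(
      roi_id = raw$roi_id, source_id = raw$source_id,
      center_x = num_col("center_x"), center_y = num_col("center_y"),
      min_x = NA_real_, min_y = NA_real_, max_x = NA_real_, max_y = NA_real_,
      label = label, score = NA_real_
    )
    cells <- add_point_boxes(cells, side = point_box_side)
  }
  validate_cell_set(cells, allow_diverse = allow_diverse)
}

#' Write a cell set to CSV (box dialect)
#'
#' Inverse of [read_annotation_csv()]: `read_annotation_csv(write_annotation_csv(s))`
#' reproduces `s` field for field. Sets without boxes get `NA` vertices
#' replaced by a 50 px box around the center so the file is always valid box
#' dialect.
#'
#' @param cells A cell-set tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_csv <- function(cells, path) {
  cells <- as_cell_set(cells, allow_diverse = TRUE)
  no_box <- is.na(cells$min_x)
  if (any(no_box)) {
    cells[no_box, ] <- add_point_boxes(cells[no_box, ], side = 50)
  }
  out <- dplyr::select(
    cells, dplyr::all_of(c("roi_id", "source_id", "min_x", "min_y",
                           "max_x", "max_y", "label", "score"))
  )
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
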