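#' Score a detection set against a reference annotation
#'
#' Detections below the score threshold are discarded, the remaining
#' detections are put in gated one-to-one correspondence with the reference
#' via [match_sets()], and per-class counts are tallied. For a class `c`:
#' TP are matched pairs labeled `c` on both sides; FN are reference cells of
#' class `c` left unmatched or matched to a detection of another class; FP
#' are detections of class `c` left unmatched (a cell that was not annotated
#' at all) or matched to a reference cell of another class.
#'
#' Reference cells labeled `"diverse"` are excluded from the evaluation
#' entirely: a preliminary matching identifies the detections paired with
#' them, both sides are removed, and the remaining sets are re-matched.
#'
#' @param reference Reference cell set (may contain diverse cells).
#' @param detections Scored cell set (`score` required on every row).
#' @param gate Matching gate in pixels.
#' @param threshold Detections with `score < threshold` are discarded.
#' @return A list with `counts` (tibble of `label`, `tp`, `fp`, `fn`),
#'   `confusion` (the [extended_confusion] over the evaluated cells) and
#'   `threshold`.
#' @export
#' @examples
#' truth <- generate_layout(n_cells = 100, seed = 1)
#' det <- simulate_detector(truth, seed = 2)$cells
#' evaluate_detections(truth, det, threshold = 0.5)$counts
evaluate_detections <- function(reference, detections, gate = 25, threshold = 0) {
  reference <- as_cell_set(reference, allow_diverse = TRUE)
  detections <- as_cell_set(detections)
  if (nrow(detections) > 0 && anyNA(detections$score)) {
    stop("detections must carry a score on every row", call. = FALSE)
  }
  detections <- detections[is.na(detections$score) | detections$score >= threshold, ,
                           drop = FALSE]

  # excise diverse reference cells together with whatever matched them
  if (any(reference$label == "diverse")) {
    pre <- match_sets(reference, detections, gate = gate)
    div <- which(reference$label == "diverse")
    det_drop <- pre$pairs$right[pre$pairs$left %in% div]
    reference <- reference[-div, , drop = FALSE]
    if (length(det_drop) > 0) detections <- detections[-det_drop, , drop = FALSE]
  }

  m <- match_sets(reference, detections, gate = gate)
  ecm <- confusion_from_match(reference, detections, m)
  cm <- unclass(ecm)
  counts <- purrr::map_dfr(seq_len(3), function(i) {
    tibble::tibble(
      label = cell_labels()[i],
      tp = cm[i, i],
      fp = sum(cm[-i, i]),          # predicted i, annotated other or missing
      fn = sum(cm[i, -i])           # annotated i, predicted other or missed
    )
  })
  list(counts = counts, confusion = ecm, threshold = threshold)
}

#' Eleven-point average precision for one cell class
#'
#' Sweeps the detection-score threshold over `0, 0.1, ..., 1` (11 points),
#' computes the precision-recall pair of the target class at each threshold
#' with [evaluate_detections()], orders the points by increasing recall and
#' accumulates the recall-increment-weighted sum of precisions:
#' `AP = sum_k (R_{k+1} - R_k) * P_k`. The curve is anchored at recall 0
#' with the precision of the strictest threshold point, a zero-width
#' segment whenever that point already sits at recall 0. Precision at a
#' threshold with no retained detections is defined as 1.
#'
#' @param reference Reference cell set (diverse cells excluded as in
#'   [evaluate_detections()]).
#' @param detections Scored cell set.
#' @param class_label One of [cell_labels()].
#' @param gate Matching gate in pixels.
#' @param thresholds Score thresholds to sweep. Default the 11-point grid;
#'   pass `"unique"` to use every distinct detection score (plus 0 and a
#'   supremum) instead.
#' @return An `ap_result`: list with `class_label`, `ap` and `points` (a
#'   tibble of `threshold`, `tp`, `fp`, `fn`, `precision`, `recall` ordered
#'   by increasing recall). `NA` ap with a warning if the reference holds no
#'   cell of the class. [tidy()] returns the PR points, [glance()] the AP.
#' @export
#' @examples
#' truth <- generate_layout(n_cells = 100, seed = 1)
#' det <- simulate_detector(truth, seed = 2)$cells
#' average_precision(truth, det, "cd3_positive")
average_precision <- function(reference, detections, class_label,
                              gate = 25, thresholds = seq(0, 1, by = 0.1)) {
  stopifnot(class_label %in% cell_labels())
  reference <- as_cell_set(reference, allow_diverse = TRUE)
  detections <- as_cell_set(detections)
  if (identical(thresholds, "unique")) {
    thresholds <- sort(unique(c(0, detections$score, 1 + 1e-9)))
  }
  n_ref <- sum(reference$label == class_label)
  if (n_ref == 0) {
    warning("no reference cells of class '", class_label,
            "': AP undefined", call. = FALSE)
    return(new_ap_result(class_label, NA_real_,
                         tibble::tibble(threshold = numeric(), tp = integer(),
                                        fp = integer(), fn = integer(),
                                        precision = numeric(), recall = numeric())))
  }
  pts <- purrr::map_dfr(thresholds, function(th) {
    cnt <- evaluate_detections(reference, detections, gate = gate,
                               threshold = th)$counts
    cnt <- cnt[cnt$label == class_label, ]
    tibble::tibble(
      threshold = th, tp = cnt$tp, fp = cnt$fp, fn = cnt$fn,
      precision = if (cnt$tp + cnt$fp > 0) cnt$tp / (cnt$tp + cnt$fp) else 1,
      recall = cnt$tp / (cnt$tp + cnt$fn)
    )
  })
  pts <- pts[order(pts$recall, -pts$threshold), , drop = FALSE]
  r <- c(0, pts$recall)
  p <- c(pts$precision[1], pts$precision)
  ap <- sum(diff(r) * p[-length(p)])
  new_ap_result(class_label, ap, pts)
}

new_ap_result <- function(class_label, ap, points) {
  structure(list(class_label = class_label, ap = ap, points = points),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("<ap_result> %s: AP = %s over %d PR points\n",
              x$class_label,
              ifelse(is.na(x$ap), "NA", sprintf("%.4f", x$ap)),
              nrow(x$points)))
  invisible(x)
}

#' @export
tidy.ap_result <- function(x, ...) {
  dplyr::mutate(x$points, class_label = x$class_label, .before = 1)
}

#' @export
glance.ap_result <- function(x, ...) {
  tibble::tibble(class_label = x$class_label, ap = x$ap,
                 n_points = nrow(x$points))
}

#' Per-class AP and its mean over classes
#'
#' Runs [average_precision()] for each of the three cell classes and
#' averages the defined APs (classes absent from the reference are reported
#' as `NA` and excluded from the mean).
#'
#' @inheritParams average_precision
#' @return A list with `per_class` (tibble of `class_label`, `ap`) and
#'   `map` (mean AP over defined classes).
#' @export
mean_average_precision <- function(reference, detections, gate = 25,
                                   thresholds = seq(0, 1, by = 0.1)) {
  per <- purrr::map_dfr(cell_labels(), function(cl) {
    ap <- suppressWarnings(
      average_precision(reference, detections, cl, gate, thresholds)
    )
    tibble::tibble(class_label = cl, ap = ap$ap)
  })
  list(per_class = per, map = mean(per$ap, na.rm = TRUE))
}

#' Greedy non-maximum suppression on cell centroids
#'
#' Repeatedly keeps the highest-scoring remaining detection and suppresses
#' every other detection (from any source) whose centroid lies within
#' `radius` pixels of it. Used to merge overlapping-patch detections and
#' model-ensemble detections into one duplicate-free set.
#'
#' @param detections One scored cell set, or a list of scored sets on the
#'   same ROI (e.g. one per ensemble member).
#' @param radius Suppression radius in pixels (default: the 25 px matching
#'   gate).
#' @return A cell-set tibble sorted by descending score, whose pairwise
#'   centroid distances all exceed `radius`.
#' @export
nms_merge <- function(detections, radius = 25) {
  if (!is.numeric(radius) || length(radius) != 1 || is.na(radius) || radius < 0) {
    stop("radius must be a non-negative number of pixels", call. = FALSE)
  }
  if (!is.data.frame(detections)) {
    detections <- dplyr::bind_rows(lapply(detections, as_cell_set))
  }
  cells <- as_cell_set(detections)
  if (nrow(cells) == 0) return(cells)
  if (anyNA(cells$score)) {
    stop("all detections must carry a score for NMS", call. = FALSE)
  }
  stop_if_mixed_roi(list(cells))
  # stable order: score desc, then original row for deterministic ties
  ord <- order(-cells$score, seq_len(nrow(cells)))
  cells <- cells[ord, , drop = FALSE]
  x <- cells$center_x; y <- cells$center_y
  n <- nrow(cells)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    close_by <- alive & (abs(x - x[i]) <= radius) & (abs(y - y[i]) <= radius)
    if (any(close_by)) {
      j <- which(close_by)
      j <- j[(x[j] - x[i])^2 + (y[j] - y[i])^2 <= radius^2]
      alive[j] <- FALSE
    }
  }
  cells[keep, , drop = FALSE]
}

#' Stitch patch-grid detections into ROI coordinates
#'
#' Translates patch-local detections into the ROI frame using each patch's
#' origin, concatenates them and removes duplicates arising in the overlap
#' strips with [nms_merge()]. Patch origins must lie on the grid implied by
#' the stride `patch_size - overlap`.
#'
#' @param patch_results A list whose elements are lists with `origin`
#'   (length-2 numeric, pixel offset of the patch's top-left corner) and
#'   `cells` (scored cell set in patch-local coordinates).
#' @param patch_size Patch side length in pixels.
#' @param overlap Overlap between adjacent patches in pixels.
#' @param nms_radius Suppression radius passed to [nms_merge()].
#' @return A duplicate-free cell-set tibble in ROI coordinates.
#' @export
stitch_patch_detections <- function(patch_results, patch_size = 256,
                                    overlap = 128, nms_radius = 25) {
  stride <- patch_size - overlap
  translated <- purrr::map(patch_results, function(p) {
    org <- p$origin
    if (any(org %% stride != 0)) {
      stop("patch origin (", org[1], ", ", org[2],
           ") is not on the stride-", stride, " grid", call. = FALSE)
    }
    cells <- as_cell_set(p$cells)
    if (nrow(cells) == 0) return(cells)
    if (any(cells$center_x < 0 | cells$center_x > patch_size |
            cells$center_y < 0 | cells$center_y > patch_size)) {
      stop("detection outside its patch bounds", call. = FALSE)
    }
    dplyr::mutate(
      cells,
      center_x = .data$center_x + org[1], center_y = .data$center_y + org[2],
      min_x = .data$min_x + org[1], min_y = .data$min_y + org[2],
      max_x = .data$max_x + org[1], max_y = .data$max_y + org[2]
    )
  })
  merged <- dplyr::bind_rows(translated)
  if (nrow(merged) == 0) return(merged)
  nms_merge(merged, radius = nms_radius)
}

#' Class-count ratio of a cell set
#'
#' Ratio of the number of cells of one class to another, e.g. the ratio of
#' CD3-positive to non-specified cells that characterizes how lymphocyte-
#' rich an indication's stroma is. Pool across ROIs by passing the combined
#' set (counts are summed before dividing).
#'
#' @param cells A cell-set tibble.
#' @param numerator,denominator Class labels (see [cell_labels()]).
#' @return A single non-negative ratio.
#' @export
#' @examples
#' truth <- generate_layout(n_cells = 200, seed = 1)
#' class_ratio(truth, "cd3_positive", "non_specified")
class_ratio <- function(cells, numerator = "cd3_positive",
                        denominator = "non_specified") {
  stopifnot(numerator %in% cell_labels(diverse = TRUE),
            denominator %in% cell_labels(diverse = TRUE))
  num <- sum(cells$label == numerator)
  den <- sum(cells$label == denominator)
  if (den == 0) stop("class ratio undefined: no '", denominator, "' cells",
                     call. = FALSE)
  num / den
}
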