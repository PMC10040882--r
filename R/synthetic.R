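#' Class-proportion presets for four tumor indications
#'
#' Three-class label proportions (tumor, CD3-positive, non-specified) whose
#' CD3-positive to non-specified ratios mirror the values observed on
#' annotated test regions of four indications: head-and-neck squamous cell
#' carcinoma 0.62, non-small-cell lung cancer 0.45, triple-negative breast
#' cancer 0.16, gastric cancer 0.37. The tumor-cell share is fixed at 0.4
#' in every preset; the remaining mass is split to realize the ratio.
#'
#' @param preset One of `"hnscc"`, `"nsclc"`, `"tnbc"`, `"gc"`.
#' @return Named numeric 3-vector summing to 1.
#' @export
#' @examples
#' p <- class_proportions_preset("tnbc")
#' p[["cd3_positive"]] / p[["non_specified"]]
class_proportions_preset <- function(preset = c("hnscc", "nsclc", "tnbc", "gc")) {
  preset <- match.arg(preset)
  ratio <- c(hnscc = 0.62, nsclc = 0.45, tnbc = 0.16, gc = 0.37)[[preset]]
  stroma <- 0.6 / (1 + ratio)
  c(tumor = 0.4, cd3_positive = ratio * stroma, non_specified = stroma)
}

#' Generate a ground-truth cell layout
#'
#' Places `n_cells` cell centers in a rectangular ROI by sequential spatial
#' inhibition (dart throwing with rejection inside `min_spacing`), the
#' hard-core point process that keeps cells from overlapping, and draws
#' class labels i.i.d. from `class_proportions`. Defaults emulate the
#' source imagery: a 2 mm^2 ROI of ~2150 x 2150 px at 0.23 um/px holding on
#' the order of a thousand annotated cells, with a 15 px minimum spacing so
#' the 25 px matching gate stays discriminative.
#'
#' @param n_cells Number of cells to place.
#' @param roi_size Length-2 vector, ROI width and height in pixels.
#' @param class_proportions Named or unnamed 3-vector of label proportions
#'   (order `tumor, cd3_positive, non_specified`), summing to 1.
#' @param min_spacing Hard-core radius in pixels; no two centers closer.
#' @param roi_id,source_id Identifiers stamped on the cells.
#' @param seed Integer seed; identical inputs give identical layouts.
#' @param max_attempts Dart-throw budget per cell before giving up.
#' @return A cell-set tibble with 50 px boxes around each center.
#' @export
#' @examples
#' truth <- generate_layout(n_cells = 100, seed = 7)
#' table(truth$label)
generate_layout <- function(n_cells = 1200, roi_size = c(2150, 2150),
                            class_proportions = class_proportions_preset("hnscc"),
                            min_spacing = 15, roi_id = "roi1",
                            source_id = "truth", seed = 1,
                            max_attempts = 200) {
  stopifnot(length(roi_size) == 2, all(roi_size > 0), min_spacing >= 0,
            length(class_proportions) == 3, all(class_proportions >= 0))
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  if (n_cells == 0) {
    return(cell_set(roi_id, source_id))
  }
  rng <- local_rng(seed)
  xs <- numeric(n_cells); ys <- numeric(n_cells)
  # gate-grid occupancy check keeps placement O(n)
  cell_sz <- max(min_spacing, 1)
  occ <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(gx, gy) paste(gx, gy)
  n_placed <- 0
  while (n_placed < n_cells) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      x <- stats::runif(1, 0, roi_size[1])
      y <- stats::runif(1, 0, roi_size[2])
      gx <- floor(x / cell_sz); gy <- floor(y / cell_sz)
      clash <- FALSE
      if (min_spacing > 0) {
        for (dx in -1:1) for (dy in -1:1) {
          pts <- occ[[key(gx + dx, gy + dy)]]
          if (!is.null(pts) &&
              any((pts$x - x)^2 + (pts$y - y)^2 < min_spacing^2)) {
            clash <- TRUE
            break
          }
        }
      }
      if (!clash) {
        n_placed <- n_placed + 1
        xs[n_placed] <- x; ys[n_placed] <- y
        k <- key(gx, gy)
        prev <- occ[[k]]
        occ[[k]] <- list(x = c(prev$x, x), y = c(prev$y, y))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", n_cells, " cells at min_spacing ", min_spacing,
           " within the ROI; lower the density", call. = FALSE)
    }
  }
  labels <- sample(cell_labels(), n_cells, replace = TRUE,
                   prob = class_proportions)
  rng$restore()
  out <- cell_set(roi_id, source_id, xs, ys, label = labels)
  add_point_boxes(out, side = 50)
}

#' Simulate a human rater on a ground-truth layout
#'
#' Emulates the two sources of inter-rater disagreement seen in cell
#' annotation: omission (each truth cell is independently missed with a
#' per-class probability) and label confusion (surviving cells get a label
#' drawn from the confusion-matrix row of their true class). Reported
#' centers are jittered with isotropic Gaussian noise.
#'
#' @param truth A ground-truth cell set from [generate_layout()].
#' @param miss_prob Per-class miss probabilities (scalar recycled to 3).
#' @param confusion 3x3 row-stochastic label confusion matrix (rows = true
#'   class, in [cell_labels()] order).
#' @param jitter_sd Standard deviation (pixels) of the center jitter.
#' @param source_id `source_id` of the simulated rater.
#' @param seed Integer seed.
#' @return A list with `cells` (the rater's cell set) and `provenance`
#'   (tibble `truth_index`, `emitted_index`, `true_label`, `given_label`;
#'   missed cells have `NA` emitted_index).
#' @export
#' @examples
#' truth <- generate_layout(n_cells = 100, seed = 1)
#' r <- simulate_rater(truth, miss_prob = 0.1, seed = 2)
#' nrow(r$cells); sum(is.na(r$provenance$emitted_index))
simulate_rater <- function(truth, miss_prob = 0.15,
                           confusion = label_confusion(0.95),
                           jitter_sd = 3, source_id = "rater", seed = 1) {
  truth <- as_cell_set(truth)
  miss_prob <- rep_len(miss_prob, 3)
  stopifnot(all(miss_prob >= 0 & miss_prob <= 1),
            identical(dim(as.matrix(confusion)), c(3L, 3L)),
            all(abs(rowSums(confusion) - 1) < 1e-8), jitter_sd >= 0)
  rng <- local_rng(seed)
  n <- nrow(truth)
  cls <- match(truth$label, cell_labels())
  missed <- stats::runif(n) < miss_prob[cls]
  given <- rep(NA_character_, n)
  for (i in which(!missed)) {
    given[i] <- sample(cell_labels(), 1, prob = confusion[cls[i], ])
  }
  kept <- which(!missed)
  jx <- stats::rnorm(length(kept), 0, jitter_sd)
  jy <- stats::rnorm(length(kept), 0, jitter_sd)
  rng$restore()
  cells <- cell_set(
    roi_id = if (n > 0) truth$roi_id[1] else "roi1",
    source_id = source_id,
    center_x = pmax(0, truth$center_x[kept] + jx),
    center_y = pmax(0, truth$center_y[kept] + jy),
    label = given[kept]
  )
  cells <- add_point_boxes(cells, side = 50)
  prov <- tibble::tibble(
    truth_index = seq_len(n),
    emitted_index = NA_integer_,
    true_label = truth$label,
    given_label = given
  )
  prov$emitted_index[kept] <- seq_along(kept)
  list(cells = cells, provenance = prov)
}

#' Symmetric label-confusion matrix
#'
#' Row-stochastic 3x3 matrix with `accuracy` on the diagonal and the
#' remaining mass split evenly over the two other classes — the
#' uniform-error ("epsilon") noise model.
#'
#' @param accuracy Probability of reporting the true class.
#' @return 3x3 matrix.
#' @export
label_confusion <- function(accuracy = 0.95) {
  stopifnot(accuracy >= 0, accuracy <= 1)
  eps <- (1 - accuracy) / 2
  m <- matrix(eps, 3, 3)
  diag(m) <- accuracy
  dimnames(m) <- list(cell_labels(), cell_labels())
  m
}

#' Simulate a cell detector on a ground-truth layout
#'
#' Each truth cell is detected with its class's recall probability, keeps
#' its true label, gets a jittered center and a confidence score drawn from
#' a Beta distribution for true detections. Clutter (false) detections are
#' added as a Poisson number of uniformly placed cells with scores from a
#' second, lower Beta distribution and uniformly random labels.
#'
#' @param truth Ground-truth cell set.
#' @param recall Per-class detection probabilities (scalar recycled to 3).
#' @param score_shape_true,score_shape_clutter Length-2 Beta shape
#'   parameters of the score distributions on `[0, 1]`.
#' @param clutter_rate Expected number of false detections on the ROI.
#' @param jitter_sd Center jitter standard deviation in pixels.
#' @param roi_size ROI extent for placing clutter.
#' @param source_id Detector identifier.
#' @param seed Integer seed.
#' @return A list with `cells` (scored cell set) and `provenance` (tibble
#'   `truth_index` — `NA` for clutter —, `emitted_index`, `true_label`).
#' @export
#' @examples
#' truth <- generate_layout(n_cells = 100, seed = 1)
#' d <- simulate_detector(truth, recall = 0.9, seed = 5)
#' mean_average_precision(truth, d$cells)$map
simulate_detector <- function(truth, recall = c(0.9, 0.92, 0.85),
                              score_shape_true = c(8, 2),
                              score_shape_clutter = c(2, 5),
                              clutter_rate = 30, jitter_sd = 2,
                              roi_size = c(2150, 2150),
                              source_id = "detector", seed = 1) {
  truth <- as_cell_set(truth)
  recall <- rep_len(recall, 3)
  stopifnot(all(recall >= 0 & recall <= 1), clutter_rate >= 0, jitter_sd >= 0)
  rng <- local_rng(seed)
  n <- nrow(truth)
  cls <- match(truth$label, cell_labels())
  hit <- stats::runif(n) < recall[cls]
  kept <- which(hit)
  k <- length(kept)
  tx <- pmax(0, truth$center_x[kept] + stats::rnorm(k, 0, jitter_sd))
  ty <- pmax(0, truth$center_y[kept] + stats::rnorm(k, 0, jitter_sd))
  ts <- stats::rbeta(k, score_shape_true[1], score_shape_true[2])
  n_clutter <- stats::rpois(1, clutter_rate)
  cx <- stats::runif(n_clutter, 0, roi_size[1])
  cy <- stats::runif(n_clutter, 0, roi_size[2])
  cs <- stats::rbeta(n_clutter, score_shape_clutter[1], score_shape_clutter[2])
  clab <- sample(cell_labels(), n_clutter, replace = TRUE)
  rng$restore()
  roi <- if (n > 0) truth$roi_id[1] else "roi1"
  cells <- cell_set(
    roi_id = roi, source_id = source_id,
    center_x = c(tx, cx), center_y = c(ty, cy),
    label = c(truth$label[kept], clab),
    score = c(ts, cs)
  )
  cells <- add_point_boxes(cells, side = 50)
  prov <- tibble::tibble(
    truth_index = c(kept, rep(NA_integer_, n_clutter)),
    emitted_index = seq_len(k + n_clutter),
    true_label = c(truth$label[kept], rep(NA_character_, n_clutter))
  )
  list(cells = cells, provenance = prov)
}

#' Simulate a complete annotated study on one ROI
#'
#' Convenience wrapper producing a ground-truth layout, three simulated
#' raters (A, B, C) and one simulated detector, with all randomness derived
#' from a single top-level seed through fixed per-component offsets so each
#' piece is independently reproducible.
#'
#' @param preset Indication preset for the class proportions (see
#'   [class_proportions_preset()]).
#' @param n_cells Cells in the ground-truth layout.
#' @param seed Top-level integer seed.
#' @param roi_id ROI identifier.
#' @param miss_prob,jitter_sd,label_accuracy Rater-model parameters; each
#'   may be a vector of 3 (one per rater).
#' @param ... Passed to [simulate_detector()].
#' @return A list with `truth`, `raters` (named list of rater outputs as in
#'   [simulate_rater()]) and `detector` ([simulate_detector()] output).
#' @export
simulate_study <- function(preset = "hnscc", n_cells = 1200, seed = 1,
                           roi_id = "roi1", miss_prob = c(0.18, 0.05, 0.20),
                           jitter_sd = c(3, 3, 3),
                           label_accuracy = c(0.95, 0.96, 0.94), ...) {
  sub <- substream_seeds(seed, 5)
  truth <- generate_layout(
    n_cells = n_cells, class_proportions = class_proportions_preset(preset),
    roi_id = roi_id, seed = sub[1]
  )
  rater_ids <- c("raterA", "raterB", "raterC")
  miss_prob <- rep_len(miss_prob, 3)
  jitter_sd <- rep_len(jitter_sd, 3)
  label_accuracy <- rep_len(label_accuracy, 3)
  raters <- purrr::map(1:3, function(i) {
    simulate_rater(truth, miss_prob = miss_prob[i],
                   confusion = label_confusion(label_accuracy[i]),
                   jitter_sd = jitter_sd[i], source_id = rater_ids[i],
                   seed = sub[1 + i])
  })
  names(raters) <- rater_ids
  detector <- simulate_detector(truth, source_id = "detector",
                                seed = sub[5], ...)
  list(truth = truth, raters = raters, detector = detector)
}

# Derive k reproducible substream seeds below 2^31 from one top-level seed.
substream_seeds <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * seq_len(k)) %% .Machine$integer.max
}

# Scoped RNG: seed on entry, restore the caller's RNG state on exit.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}
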