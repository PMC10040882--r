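perfect_detections <- function(truth, source_id = "det") {
  dplyr::mutate(truth, source_id = source_id, score = 1)
}

test_that("a perfect detector scores TP on every class and AP 1", {
  truth <- generate_layout(n_cells = 150, seed = 2)
  det <- perfect_detections(truth)
  res <- evaluate_detections(truth, det, threshold = 0)
  expect_equal(res$counts$tp,
               as.vector(table(factor(truth$label, cell_labels()))))
  expect_equal(res$counts$fp, rep(0L, 3))
  expect_equal(res$counts$fn, rep(0L, 3))
  for (cl in cell_labels()) {
    expect_equal(average_precision(truth, det, cl)$ap, 1)
  }
})

test_that("unannotated detections are FP; all-FP detectors get AP 0", {
  empty_ref <- cell_set("roi1", "truth")
  det <- cell_set("roi1", "det", 10, 10, label = "tumor", score = 0.9)
  res <- evaluate_detections(empty_ref, det)
  expect_equal(res$counts$fp[res$counts$label == "tumor"], 1L)

  truth <- generate_layout(n_cells = 50, seed = 3)
  clutter <- simulate_detector(truth, recall = 0, clutter_rate = 60,
                               seed = 4)$cells
  ap <- average_precision(truth, clutter, "tumor")
  expect_equal(ap$ap, 0)
})

test_that("planted detector counts are recovered exactly from provenance", {
  truth <- generate_layout(n_cells = 500, seed = 10)
  sim <- simulate_detector(truth, recall = c(0.8, 0.9, 0.7),
                           clutter_rate = 40, jitter_sd = 2, seed = 11)
  res <- evaluate_detections(truth, sim$cells, threshold = 0)
  prov <- sim$provenance
  hits <- prov[!is.na(prov$truth_index), ]
  for (i in 1:3) {
    cl <- cell_labels()[i]
    n_true <- sum(truth$label == cl)
    n_hit <- sum(hits$true_label == cl)
    row <- res$counts[res$counts$label == cl, ]
    expect_equal(row$tp + row$fn, n_true)  # conservation
    # all jittered true detections sit within the gate, so TP >= planted
    # hits minus any label-free clutter interactions; at these densities
    # the counts match the bookkeeping exactly
    expect_gte(row$tp, n_hit - 5)
  }
})

test_that("TP+FN equals the class reference count at every threshold", {
  truth <- generate_layout(n_cells = 300, seed = 12)
  det <- simulate_detector(truth, seed = 13)$cells
  ref_counts <- as.vector(table(factor(truth$label, cell_labels())))
  for (th in c(0, 0.3, 0.7, 1)) {
    cnt <- evaluate_detections(truth, det, threshold = th)$counts
    expect_equal(cnt$tp + cnt$fn, ref_counts)
  }
})

test_that("eleven-point AP equals a hand-tallied PR evaluation", {
  # 20-cell toy instance on a line, far apart, with chosen scores
  set.seed(0)
  n <- 20
  truth <- cell_set("r", "t", seq(0, by = 100, length.out = n), 0,
                    label = rep("tumor", n))
  # detections: first 14 true positions, last 6 displaced beyond the gate
  scores <- c(0.95, 0.9, 0.85, 0.8, 0.75, 0.7, 0.65, 0.6, 0.55, 0.5,
              0.45, 0.4, 0.35, 0.3, 0.88, 0.66, 0.44, 0.22, 0.12, 0.02)
  det <- cell_set("r", "d",
                  c(seq(0, by = 100, length.out = 14),
                    seq(50, by = 100, length.out = 6)),
                  0, label = "tumor", score = scores)
  ap <- average_precision(truth, det, "tumor")

  # oracle: direct tally per threshold (TP = true detections kept, FP =
  # displaced detections kept), eq over increasing recall
  oracle_pts <- t(vapply(seq(0, 1, by = 0.1), function(th) {
    tp <- sum(scores[1:14] >= th)
    fp <- sum(scores[15:20] >= th)
    c(prec = if (tp + fp > 0) tp / (tp + fp) else 1, rec = tp / n)
  }, c(prec = 0, rec = 0)))
  o <- oracle_pts[order(oracle_pts[, "rec"]), ]
  r <- c(0, o[, "rec"]); p <- c(o[1, "prec"], o[, "prec"])
  ap_oracle <- sum(diff(r) * p[-length(p)])
  expect_equal(ap$ap, ap_oracle, tolerance = 1e-12)
  expect_equal(nrow(ap$points), 11)
  expect_true(all(diff(ap$points$recall) >= 0))
})

test_that("AP ignores monotone score transforms that keep threshold bins", {
  truth <- generate_layout(n_cells = 120, seed = 30)
  det <- simulate_detector(truth, seed = 31)$cells
  ap1 <- average_precision(truth, det, "tumor")$ap
  # shift scores within their 0.1-wide bin: bin assignment is unchanged
  det2 <- dplyr::mutate(det, score = pmin(1, floor(score * 10) / 10 + 0.049))
  ap2 <- average_precision(truth, det2, "tumor")$ap
  expect_equal(ap1, ap2, tolerance = 1e-12)
})

test_that("AP never increases when the gate shrinks", {
  truth <- generate_layout(n_cells = 200, seed = 33)
  det <- simulate_detector(truth, jitter_sd = 6, seed = 34)$cells
  aps <- vapply(c(40, 25, 12, 6), function(g) {
    average_precision(truth, det, "non_specified", gate = g)$ap
  }, numeric(1))
  expect_true(all(diff(aps) <= 1e-12))
})

test_that("AP for an absent class is reported as NA, not zero", {
  truth <- cell_set("r", "t", c(1, 50), c(1, 50), label = "tumor")
  det <- perfect_detections(truth)
  expect_warning(ap <- average_precision(truth, det, "cd3_positive"),
                 "undefined")
  expect_true(is.na(ap$ap))
  mAP <- mean_average_precision(truth, det)
  expect_equal(mAP$map, 1)  # only defined classes enter the mean
})

test_that("diverse reference cells and their detections are excised", {
  ref <- cell_set("r", "cons", c(10, 200), c(10, 200),
                  label = c("diverse", "tumor"), allow_diverse = TRUE)
  det <- cell_set("r", "d", c(12, 201), c(11, 201),
                  label = c("tumor", "tumor"), score = c(0.9, 0.8))
  res <- evaluate_detections(ref, det)
  # the detection on the diverse cell is neither TP nor FP
  expect_equal(res$counts$tp[1], 1L)
  expect_equal(res$counts$fp[1], 0L)
  expect_equal(sum(res$counts$fn), 0L)
})

test_that("greedy NMS equals an exhaustive oracle and separates survivors", {
  set.seed(40)
  for (rep in 1:15) {
    n <- sample(5:25, 1)
    det <- cell_set("r", "d", runif(n, 0, 120), runif(n, 0, 120),
                    label = sample(cell_labels(), n, replace = TRUE),
                    score = runif(n))
    radius <- sample(c(10, 25), 1)
    got <- nms_merge(det, radius = radius)

    # direct greedy re-implementation
    remaining <- det[order(-det$score), ]
    kept <- remaining[0, ]
    while (nrow(remaining) > 0) {
      top <- remaining[1, ]
      kept <- rbind(kept, top)
      d2 <- (remaining$center_x - top$center_x)^2 +
        (remaining$center_y - top$center_y)^2
      remaining <- remaining[d2 > radius^2, ]
    }
    expect_equal(as.data.frame(got), as.data.frame(kept), ignore_attr = TRUE)
    if (nrow(got) > 1) {
      dmat <- as.matrix(stats::dist(got[, c("center_x", "center_y")]))
      expect_true(all(dmat[upper.tri(dmat)] > radius))
    }
  }
})

test_that("NMS keeps isolated detections and dedupes exact copies", {
  det <- cell_set("r", "d", c(0, 100, 200), c(0, 0, 0),
                  label = "tumor", score = c(0.5, 0.9, 0.7))
  out <- nms_merge(det, radius = 25)
  expect_equal(nrow(out), 3)
  expect_equal(out$score, c(0.9, 0.7, 0.5))  # sorted by descending score

  twice <- list(det, dplyr::mutate(det, source_id = "d2"))
  merged <- nms_merge(twice, radius = 25)
  expect_equal(nrow(merged), 3)
  expect_error(nms_merge(det, radius = -2), "radius")
})

test_that("patch stitching translates coordinates and removes overlap twins", {
  one <- list(origin = c(128, 256),
              cells = cell_set("r", "d", 30, 40, label = "tumor", score = 0.8))
  out <- stitch_patch_detections(list(one))
  expect_equal(out$center_x, 158)
  expect_equal(out$center_y, 296)

  # same physical cell seen by two adjacent overlapping patches
  p1 <- list(origin = c(0, 0),
             cells = cell_set("r", "d", 200, 50, label = "tumor", score = 0.9))
  p2 <- list(origin = c(128, 0),
             cells = cell_set("r", "d", 72, 50, label = "tumor", score = 0.7))
  out <- stitch_patch_detections(list(p1, p2))
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 0.9)

  bad <- list(origin = c(64, 0), cells = p1$cells)
  expect_error(stitch_patch_detections(list(bad)), "grid")
  outside <- list(origin = c(0, 0),
                  cells = cell_set("r", "d", 300, 10, label = "tumor",
                                   score = 0.5))
  expect_error(stitch_patch_detections(list(outside)), "bounds")
})

test_that("planted duplicates in overlap strips collapse to unique cells", {
  set.seed(50)
  truth <- generate_layout(n_cells = 120, roi_size = c(512, 512), seed = 51)
  stride <- 128; patch <- 256
  origins <- expand.grid(x = seq(0, 512 - patch, by = stride),
                         y = seq(0, 512 - patch, by = stride))
  patches <- purrr::pmap(origins, function(x, y) {
    inside <- truth$center_x >= x & truth$center_x <= x + patch &
      truth$center_y >= y & truth$center_y <= y + patch
    cells <- dplyr::mutate(truth[inside, ],
                           center_x = center_x - x, center_y = center_y - y,
                           min_x = min_x - x, max_x = max_x - x,
                           min_y = min_y - y, max_y = max_y - y,
                           score = 0.9)
    list(origin = c(x, y), cells = cells)
  })
  merged <- stitch_patch_detections(patches, patch_size = patch,
                                    overlap = patch - stride, nms_radius = 10)
  expect_equal(nrow(merged), 120)  # every planted cell once
  expect_equal(sort(round(merged$center_x, 6)),
               sort(round(truth$center_x, 6)))
})

test_that("class ratios divide pooled counts", {
  s <- cell_set("r", "t", seq(20, by = 20, length.out = 20), 10,
                label = c(rep("cd3_positive", 10), rep("non_specified", 10)))
  expect_equal(class_ratio(s, "cd3_positive", "non_specified"), 1)
  s2 <- cell_set("r", "t", seq(20, by = 20, length.out = 116), 10,
                 label = c(rep("cd3_positive", 16), rep("non_specified", 100)))
  expect_equal(class_ratio(s2, "cd3_positive", "non_specified"), 0.16)
  expect_error(class_ratio(s2, "non_specified", "tumor"), "undefined")
})

test_that("configured class mixes are recovered from generated layouts", {
  p <- class_proportions_preset("hnscc")
  truth <- generate_layout(n_cells = 5000, roi_size = c(4500, 4500),
                           class_proportions = p, seed = 60)
  ratio <- class_ratio(truth, "cd3_positive", "non_specified")
  # 3 binomial SEs on the component proportions at n = 5000
  expect_equal(ratio, 0.62, tolerance = 0.1)
})
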