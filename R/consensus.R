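#' Build a consensus annotation set from several raters
#'
#' Under the assumption that raters rarely hallucinate cells, every cell
#' annotated by any rater enters the consensus. Cells from different raters
#' are identified as the same physical cell by sequentially folding each
#' rater into the evolving consensus with the same gated optimal matching
#' used everywhere else ([match_sets()], default gate 25 px) against the
#' current cluster centroids; raters are processed in lexicographic
#' `source_id` order for determinism. A cluster never contains two cells of
#' the same rater.
#'
#' Labels are decided by majority vote over cluster members. A draw — most
#' commonly a cell annotated by exactly two raters who assigned different
#' labels, but also a three-way split — yields the separate label
#' `"diverse"`. Clusters supported by a single rater keep that rater's
#' label.
#'
#' @param sets A list of cell-set tibbles (one per rater) or a single
#'   combined tibble with several `source_id`s; all on one ROI.
#' @param gate Matching gate in pixels.
#' @param rater_order Optional character vector overriding the processing
#'   order (useful for measuring order sensitivity).
#' @param source_id `source_id` given to the consensus cells.
#' @return A cell-set tibble whose rows are consensus cells (centers =
#'   cluster centroids, label possibly `"diverse"`), with extra columns
#'   `support` (number of contributing raters) and `members` (list column
#'   of per-member `source_id` / row-index pairs).
#' @export
#' @examples
#' truth <- generate_layout(n_cells = 60, seed = 1)
#' raters <- lapply(c("A", "B", "C"), function(id)
#'   simulate_rater(truth, source_id = id, seed = match(id, LETTERS))$cells)
#' cons <- build_consensus(raters)
#' diverse_fraction(cons)
build_consensus <- function(sets, gate = 25, rater_order = NULL,
                            source_id = "consensus") {
  sources <- split_sources(sets)
  if (length(sources) < 2) stop("need at least two raters", call. = FALSE)
  stop_if_mixed_roi(sources)
  order_ids <- if (is.null(rater_order)) sort(names(sources)) else rater_order
  stopifnot(setequal(order_ids, names(sources)))

  roi <- unique(unlist(lapply(sources, function(s) unique(s$roi_id))))
  if (length(roi) == 0) roi <- NA_character_

  # clusters: running centroid plus member bookkeeping
  first <- sources[[order_ids[1]]]
  clusters <- list(
    x = first$center_x, y = first$center_y,
    members = lapply(seq_len(nrow(first)), function(i) {
      tibble::tibble(source_id = order_ids[1], index = i, label = first$label[i])
    })
  )

  for (id in order_ids[-1]) {
    s <- sources[[id]]
    if (nrow(s) == 0) next
    if (length(clusters$x) == 0) {
      clusters$x <- s$center_x
      clusters$y <- s$center_y
      clusters$members <- lapply(seq_len(nrow(s)), function(i) {
        tibble::tibble(source_id = id, index = i, label = s$label[i])
      })
      next
    }
    centroids <- cell_set(roi, "centroid", clusters$x, clusters$y,
                          label = "tumor")
    m <- match_sets(centroids, s, gate = gate)
    for (k in seq_len(nrow(m$pairs))) {
      ci <- m$pairs$left[k]; si <- m$pairs$right[k]
      clusters$members[[ci]] <- dplyr::bind_rows(
        clusters$members[[ci]],
        tibble::tibble(source_id = id, index = si, label = s$label[si])
      )
      n_mem <- nrow(clusters$members[[ci]])
      # running centroid over all member coordinates
      clusters$x[ci] <- (clusters$x[ci] * (n_mem - 1) + s$center_x[si]) / n_mem
      clusters$y[ci] <- (clusters$y[ci] * (n_mem - 1) + s$center_y[si]) / n_mem
    }
    for (si in m$unmatched_right) {
      clusters$x <- c(clusters$x, s$center_x[si])
      clusters$y <- c(clusters$y, s$center_y[si])
      clusters$members <- c(clusters$members, list(
        tibble::tibble(source_id = id, index = si, label = s$label[si])
      ))
    }
  }

  vote <- vapply(clusters$members, function(mem) {
    tab <- sort(table(mem$label), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) "diverse" else names(tab)[1]
  }, character(1))
  support <- vapply(clusters$members, nrow, integer(1))

  out <- cell_set(
    roi_id = roi, source_id = source_id,
    center_x = clusters$x, center_y = clusters$y,
    label = if (length(vote) > 0) vote else character(),
    allow_diverse = TRUE
  )
  out <- add_point_boxes(out, side = 50)
  out$support <- support
  out$members <- clusters$members
  out
}

#' Fraction of consensus cells with the tie label
#'
#' Proportion of cells in a consensus set whose label is `"diverse"`, i.e.
#' cells on which the raters tied without a plurality. With multi-ROI input
#' the per-ROI fractions and their mean and standard deviation are also of
#' interest; see `by_roi`.
#'
#' @param consensus A consensus cell set from [build_consensus()] (one or
#'   more ROIs).
#' @param by_roi If `TRUE`, return a per-ROI tibble plus mean/sd instead of
#'   a single number.
#' @return A proportion in `[0, 1]`, or (with `by_roi = TRUE`) a list with
#'   `per_roi` (tibble of `roi_id`, `fraction`), `mean` and `sd`.
#' @export
diverse_fraction <- function(consensus, by_roi = FALSE) {
  if (nrow(consensus) == 0) {
    stop("diverse fraction undefined for an empty consensus", call. = FALSE)
  }
  if (!by_roi) {
    return(mean(consensus$label == "diverse"))
  }
  per <- consensus |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::summarise(fraction = mean(.data$label == "diverse"), .groups = "drop")
  list(per_roi = per, mean = mean(per$fraction), sd = stats::sd(per$fraction))
}
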