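#' Cohen's kappa and its missed-cell variants
#'
#' Chance-corrected inter-rater agreement, `kappa = (Po - Pe) / (1 - Pe)`,
#' computed from a confusion matrix. Four variants are available for the
#' cell-annotation setting where a cell may have been labeled by only one of
#' the two raters (the virtual `missing` class of
#' [confusion_from_match()]):
#'
#' * **standard** — plain Cohen's kappa on a 3x3 matrix of jointly labeled
#'   cells; `Po = sum(n_ii) / N`, `Pe = sum(n_i. * n_.i) / N^2`.
#' * **regular_category** — treats `missing` as a fourth class and leaves
#'   the computation otherwise unchanged. Since no cell is missing from
#'   both raters, the missing-missing diagonal term is structurally zero,
#'   so omissions can only lower agreement.
#' * **listwise_deletion** — restricts both `Po` and `Pe` to cells labeled
#'   by both raters (the 3x3 core), with margins corrected by the missing
#'   row/column.
#' * **gwet** — `Po` over jointly labeled cells as in listwise deletion,
#'   but `Pe` uses the full margins normalized by `(N - n_t.) * (N - n_.t)`,
#'   so singly-labeled cells still inform the chance term.
#'
#' All four coincide when no cell is missing on either side.
#'
#' @param cm A 3x3 count matrix (rows = rater A, columns = rater B) over
#'   `tumor, cd3_positive, non_specified`.
#' @param ecm An `extended_confusion` 4x4 matrix (see
#'   [confusion_from_match()]).
#' @return A `kappa_result` object with fields `variant`, `po`, `pe`,
#'   `kappa`, `interpretation` (Landis-Koch) and `n_effective` (cells
#'   entering `Po`). Use [tidy()] for a one-row tibble.
#' @seealso [interpret_kappa()], [pairwise_agreement_report()]
#' @export
#' @examples
#' kappa_standard(diag(c(10, 10, 10)))
#' m <- rbind(c(20, 5, 0), c(5, 20, 5), c(0, 5, 40))
#' kappa_standard(m)
kappa_standard <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(identical(dim(cm), c(3L, 3L)))
  n <- sum(cm)
  if (n == 0) stop("kappa undefined: empty confusion matrix", call. = FALSE)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  new_kappa_result("standard", po, pe, n_effective = n)
}

#' @rdname kappa_standard
#' @export
kappa_regular_category <- function(ecm) {
  m <- as_ecm_counts(ecm)
  n <- sum(m)
  if (n == 0) stop("kappa undefined: empty confusion matrix", call. = FALSE)
  po <- (sum(diag(m)[1:3]) + m[4, 4]) / n
  pe <- (sum(rowSums(m)[1:3] * colSums(m)[1:3]) + rowSums(m)[4] * colSums(m)[4]) / n^2
  new_kappa_result("regular_category", po, pe, n_effective = n)
}

#' @rdname kappa_standard
#' @export
kappa_listwise_deletion <- function(ecm) {
  m <- as_ecm_counts(ecm)
  core <- m[1:3, 1:3]
  nc <- sum(core)
  if (nc == 0) {
    stop("kappa undefined: no cells labeled by both raters", call. = FALSE)
  }
  po <- sum(diag(core)) / nc
  pe <- sum((rowSums(m)[1:3] - m[1:3, 4]) * (colSums(m)[1:3] - m[4, 1:3])) / nc^2
  new_kappa_result("listwise_deletion", po, pe, n_effective = nc)
}

#' @rdname kappa_standard
#' @export
kappa_gwet <- function(ecm) {
  m <- as_ecm_counts(ecm)
  core <- m[1:3, 1:3]
  nc <- sum(core)
  n <- sum(m)
  if (nc == 0) {
    stop("kappa undefined: no cells labeled by both raters", call. = FALSE)
  }
  denom <- (n - rowSums(m)[4]) * (n - colSums(m)[4])
  if (denom == 0) {
    stop("kappa undefined: a rater labeled no cells", call. = FALSE)
  }
  po <- sum(diag(core)) / nc
  pe <- sum(rowSums(m)[1:3] * colSums(m)[1:3]) / denom
  new_kappa_result("gwet", po, pe, n_effective = nc)
}

as_ecm_counts <- function(ecm) {
  m <- unclass(as.matrix(ecm))
  stopifnot(identical(dim(m), c(4L, 4L)))
  m
}

new_kappa_result <- function(variant, po, pe, n_effective) {
  po <- unname(po); pe <- unname(pe); n_effective <- unname(n_effective)
  if (pe >= 1) {
    stop("kappa undefined: expected agreement Pe = 1", call. = FALSE)
  }
  k <- (po - pe) / (1 - pe)
  structure(
    list(variant = variant, po = po, pe = pe, kappa = k,
         interpretation = interpret_kappa(k), n_effective = n_effective),
    class = "kappa_result"
  )
}

#' Landis-Koch interpretation of a kappa score
#'
#' Maps kappa to the conventional agreement strength intervals:
#' below 0 poor, (0, 0.2] slight, (0.2, 0.4] fair, (0.4, 0.6] moderate,
#' (0.6, 0.8] substantial, (0.8, 1] almost perfect. A kappa of exactly 0
#' (chance-level) is assigned to `slight`, the interval whose boundary it
#' sits on.
#'
#' @param kappa Numeric kappa value(s), each at most 1.
#' @return Character vector of interpretations.
#' @export
#' @examples
#' interpret_kappa(c(-0.1, 0.5, 1))
interpret_kappa <- function(kappa) {
  stopifnot(all(kappa <= 1 + 1e-12))
  cut_pts <- c(-Inf, 0 - .Machine$double.eps, 0.2, 0.4, 0.6, 0.8, 1 + 1e-12)
  labels <- c("poor", "slight", "fair", "moderate", "substantial", "almost_perfect")
  as.character(cut(kappa, breaks = cut_pts, labels = labels, right = TRUE))
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> %s: kappa = %.4f (Po = %.4f, Pe = %.4f, n = %d) [%s]\n",
              x$variant, x$kappa, x$po, x$pe, x$n_effective, x$interpretation))
  invisible(x)
}

#' @export
tidy.kappa_result <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, po = x$po, pe = x$pe, kappa = x$kappa,
    interpretation = x$interpretation, n_effective = x$n_effective
  )
}

#' @export
glance.kappa_result <- function(x, ...) tidy(x)

kappa_all_variants <- function(ecm) {
  safe <- function(f) tryCatch(tidy(f(ecm)), error = function(e) NULL)
  core <- as_ecm_counts(ecm)[1:3, 1:3]
  std <- tryCatch(tidy(kappa_standard(core)), error = function(e) NULL)
  dplyr::bind_rows(std, safe(kappa_regular_category),
                   safe(kappa_listwise_deletion), safe(kappa_gwet))
}

#' Pairwise agreement report for several raters
#'
#' For every unordered pair of sources: match the two sets with
#' [match_sets()], tally the extended confusion matrix and compute all four
#' kappa variants. Multi-ROI input is supported; with `pooled = TRUE`
#' (default) confusion counts are summed over ROIs before computing kappa
#' (micro-averaging), otherwise one row per ROI and pair is returned.
#' Diverse-labeled cells are dropped before matching.
#'
#' @param sets A list of cell-set tibbles, or one combined tibble holding
#'   several `source_id`s.
#' @param gate Matching gate in pixels.
#' @param pooled Pool confusion counts across ROIs before computing kappa.
#' @return A tibble with columns `left_source`, `right_source` (and `roi_id`
#'   when `pooled = FALSE`), `variant`, `po`, `pe`, `kappa`,
#'   `interpretation`, `n_effective`. Variants whose statistic is undefined
#'   on a pair (e.g. no jointly labeled cells) are omitted for that pair.
#' @export
#' @examples
#' truth <- generate_layout(n_cells = 80, seed = 1)
#' r1 <- simulate_rater(truth, source_id = "A", seed = 2)$cells
#' r2 <- simulate_rater(truth, source_id = "B", seed = 3)$cells
#' pairwise_agreement_report(list(r1, r2))
pairwise_agreement_report <- function(sets, gate = 25, pooled = TRUE) {
  sources <- split_sources(sets)
  sources <- lapply(sources, function(s) s[s$label != "diverse", , drop = FALSE])
  ids <- sort(names(sources))
  if (length(ids) < 2) stop("need at least two sources", call. = FALSE)

  pair_tbl <- function(a, b, roi = NULL) {
    sa <- sources[[a]]; sb <- sources[[b]]
    if (!is.null(roi)) {
      sa <- sa[sa$roi_id == roi, , drop = FALSE]
      sb <- sb[sb$roi_id == roi, , drop = FALSE]
    }
    ecm_by_roi <- function(sa, sb) {
      rois <- union(unique(sa$roi_id), unique(sb$roi_id))
      m <- matrix(0L, 4, 4)
      for (r in rois) {
        la <- sa[sa$roi_id == r, , drop = FALSE]
        lb <- sb[sb$roi_id == r, , drop = FALSE]
        m <- m + unclass(confusion_from_match(la, lb, match_sets(la, lb, gate)))
      }
      extended_confusion(m, a, b)
    }
    res <- kappa_all_variants(ecm_by_roi(sa, sb))
    if (nrow(res) == 0) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(left_source = a, right_source = b,
                     roi_id = if (is.null(roi)) NA_character_ else roi)[rep(1, nrow(res)), ],
      res
    )
  }

  combos <- utils::combn(ids, 2, simplify = FALSE)
  if (pooled) {
    out <- purrr::map(combos, ~ pair_tbl(.x[1], .x[2]))
    out <- dplyr::bind_rows(out)
    out$roi_id <- NULL
  } else {
    rois <- sort(unique(unlist(lapply(sources, function(s) unique(s$roi_id)))))
    out <- dplyr::bind_rows(purrr::map(combos, function(p) {
      dplyr::bind_rows(purrr::map(rois, ~ pair_tbl(p[1], p[2], roi = .x)))
    }))
  }
  out
}
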