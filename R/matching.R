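#' Distance-gated optimal correspondence between two cell sets
#'
#' Builds the Euclidean centroid-to-centroid distance matrix between the two
#' sets and solves the minimum-total-distance one-to-one assignment
#' (Hungarian/Jonker-Volgenant). A pair only counts as the same cell when
#' the two centroids lie within `gate` pixels of each other (default 25 px,
#' the radius of an average cell at 0.23 um/px).
#'
#' With `method = "pregate"` (default) distances beyond the gate are
#' forbidden before solving, so the result is a maximal-cardinality,
#' minimum-cost matching among gate-feasible pairings. With
#' `method = "postgate"` the unrestricted global assignment is solved first
#' and pairs beyond the gate are then dissolved into unmatched entries;
#' this can discard pairs a feasible matching would keep and exists for
#' comparison only.
#'
#' Pre-gated matching decomposes over connected components of the
#' within-gate candidate graph, which keeps ROI-scale inputs (thousands of
#' cells) fast without changing the optimum.
#'
#' @param left,right Cell-set tibbles (see [cell_set()]); diverse-labeled
#'   cells are permitted, filtering is the caller's concern.
#' @param gate Maximum centroid distance in pixels for a valid pair.
#' @param method `"pregate"` or `"postgate"` (see Details).
#' @return An object of class `cell_match`: a list with `pairs` (tibble of
#'   `left`, `right` row indices and `distance`), integer vectors
#'   `unmatched_left` / `unmatched_right`, and `gate`. [tidy()] turns it
#'   into one long tibble.
#' @export
#' @examples
#' a <- cell_set("r", "A", c(0, 100), c(0, 100), label = "tumor")
#' b <- cell_set("r", "B", c(3, 250), c(4, 250), label = "tumor")
#' match_sets(a, b)
match_sets <- function(left, right, gate = 25, method = c("pregate", "postgate")) {
  method <- match.arg(method)
  if (!is.numeric(gate) || length(gate) != 1 || is.na(gate) || gate <= 0) {
    stop("gate must be a positive number of pixels", call. = FALSE)
  }
  left <- as_cell_set(left, allow_diverse = TRUE)
  right <- as_cell_set(right, allow_diverse = TRUE)
  nl <- nrow(left); nr <- nrow(right)

  if (nl == 0 || nr == 0) {
    return(new_cell_match(
      tibble::tibble(left = integer(), right = integer(), distance = numeric()),
      seq_len(nl), seq_len(nr), gate
    ))
  }

  if (method == "postgate") {
    d <- outer(left$center_x, right$center_x, "-")^2 +
      outer(left$center_y, right$center_y, "-")^2
    d <- sqrt(d)
    res <- solve_rect_lap(d)
    keep <- res$distance <= gate
    pairs <- res[keep, , drop = FALSE]
  } else {
    cand <- gate_candidates(left, right, gate)
    pairs <- match_components(left, right, cand, gate)
  }
  pairs <- pairs[order(pairs$left), , drop = FALSE]
  new_cell_match(
    tibble::as_tibble(pairs),
    setdiff(seq_len(nl), pairs$left),
    setdiff(seq_len(nr), pairs$right),
    gate
  )
}

new_cell_match <- function(pairs, unmatched_left, unmatched_right, gate) {
  structure(
    list(pairs = pairs,
         unmatched_left = as.integer(unmatched_left),
         unmatched_right = as.integer(unmatched_right),
         gate = gate),
    class = "cell_match"
  )
}

#' @export
print.cell_match <- function(x, ...) {
  cat("<cell_match> gate =", x$gate, "px\n")
  cat("  pairs:", nrow(x$pairs),
      " unmatched left:", length(x$unmatched_left),
      " unmatched right:", length(x$unmatched_right), "\n")
  invisible(x)
}

# All (i, j) index pairs whose centroids are within `gate`, found by binning
# both sets on a gate-sized grid and joining each left bin with its 3x3
# neighborhood. Avoids the full nl x nr distance matrix.
gate_candidates <- function(left, right, gate) {
  rb <- tibble::tibble(
    j = seq_len(nrow(right)),
    bx = floor(right$center_x / gate),
    by = floor(right$center_y / gate)
  )
  off <- tidyr::expand_grid(dx = -1:1, dy = -1:1)
  lb <- tibble::tibble(
    i = seq_len(nrow(left)),
    lx = floor(left$center_x / gate),
    ly = floor(left$center_y / gate)
  )
  lb <- tidyr::crossing(lb, off)
  lb$bx <- lb$lx + lb$dx
  lb$by <- lb$ly + lb$dy
  cand <- dplyr::inner_join(lb[, c("i", "bx", "by")], rb, by = c("bx", "by"),
                            relationship = "many-to-many")
  if (nrow(cand) == 0) {
    return(tibble::tibble(i = integer(), j = integer(), distance = numeric()))
  }
  cand$distance <- sqrt(
    (left$center_x[cand$i] - right$center_x[cand$j])^2 +
      (left$center_y[cand$i] - right$center_y[cand$j])^2
  )
  cand <- cand[cand$distance <= gate, c("i", "j", "distance")]
  tibble::as_tibble(cand)
}

# Solve the gated assignment independently on each connected component of
# the candidate graph; exact because no feasible pair crosses components.
match_components <- function(left, right, cand, gate) {
  empty <- tibble::tibble(left = integer(), right = integer(), distance = numeric())
  if (nrow(cand) == 0) return(empty)
  nl <- nrow(left)
  comp <- union_find_components(cand$i, cand$j + nl, nl + nrow(right))
  cand$comp <- comp[cand$i]

  out <- lapply(split(cand, cand$comp), function(cc) {
    li <- sort(unique(cc$i)); rj <- sort(unique(cc$j))
    if (length(li) == 1 && length(rj) == 1) {
      return(data.frame(left = li, right = rj, distance = cc$distance[1]))
    }
    n <- max(length(li), length(rj))
    big <- gate * (n + 1) + 1  # dominates any feasible total cost
    cost <- matrix(big, n, n)
    if (length(li) < n) cost[(length(li) + 1):n, ] <- 0
    if (length(rj) < n) cost[, (length(rj) + 1):n] <- 0
    cost[cbind(match(cc$i, li), match(cc$j, rj))] <- cc$distance
    sol <- lap_solve(cost)
    ii <- seq_along(li)
    jj <- sol[ii]
    keep <- jj <= length(rj) & cost[cbind(ii, jj)] <= gate
    data.frame(left = li[ii[keep]], right = rj[jj[keep]],
               distance = cost[cbind(ii[keep], jj[keep])])
  })
  tibble::as_tibble(do.call(rbind, c(out, list(make.row.names = FALSE))))
}

# Plain iterative union-find; edges (a[k], b[k]) over n vertices.
union_find_components <- function(a, b, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[rb] <- ra
  }
  vapply(seq_len(n), find, integer(1))
}

# Unrestricted rectangular assignment (used by the postgate mode): pad to
# square with zero-cost dummies, solve, return real-real pairs.
solve_rect_lap <- function(d) {
  nl <- nrow(d); nr <- ncol(d)
  n <- max(nl, nr)
  cost <- matrix(0, n, n)
  cost[seq_len(nl), seq_len(nr)] <- d
  sol <- lap_solve(cost)
  i <- seq_len(nl)
  j <- sol[i]
  keep <- j <= nr
  data.frame(left = i[keep], right = j[keep],
             distance = d[cbind(i[keep], j[keep])])
}

#' @export
tidy.cell_match <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$pairs, status = "paired"),
    tibble::tibble(left = x$unmatched_left, right = NA_integer_,
                   distance = NA_real_, status = "unmatched_left"),
    tibble::tibble(left = NA_integer_, right = x$unmatched_right,
                   distance = NA_real_, status = "unmatched_right")
  )
}
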