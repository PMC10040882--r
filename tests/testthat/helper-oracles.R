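# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: exhaustive enumeration for the gated assignment,
# and literal sum-by-sum evaluation of the kappa formulas.

# Exhaustive gated matching: every injective partial assignment of left
# cells to right cells with pair distance <= gate; maximal cardinality
# first, then minimal total distance. Returns a data.frame of pairs.
brute_force_match <- function(left, right, gate) {
  nl <- nrow(left); nr <- nrow(right)
  d <- sqrt(outer(left$center_x, right$center_x, "-")^2 +
              outer(left$center_y, right$center_y, "-")^2)
  best_card <- -1L
  best_cost <- Inf
  best_assign <- integer(nl)
  assign <- integer(nl)  # right index per left cell, 0 = unmatched
  used <- rep(FALSE, nr)
  recurse <- function(i, card, cost) {
    if (i > nl) {
      if (card > best_card || (card == best_card && cost < best_cost - 1e-12)) {
        best_card <<- card
        best_cost <<- cost
        best_assign <<- assign
      }
      return(invisible())
    }
    # leave left cell i unmatched
    assign[i] <<- 0L
    recurse(i + 1L, card, cost)
    for (j in seq_len(nr)) {
      if (!used[j] && d[i, j] <= gate) {
        used[j] <<- TRUE
        assign[i] <<- j
        recurse(i + 1L, card + 1L, cost + d[i, j])
        used[j] <<- FALSE
        assign[i] <<- 0L
      }
    }
  }
  recurse(1L, 0L, 0)
  i <- which(best_assign > 0L)
  list(card = best_card, cost = best_cost,
       pairs = data.frame(left = i, right = best_assign[i]))
}

# Random small matching instance on a compact square so gate interactions
# are frequent.
random_instance <- function(n_left, n_right, extent = 100, source = c("A", "B")) {
  list(
    left = cell_set("roi1", source[1],
                    runif(n_left, 0, extent), runif(n_left, 0, extent),
                    label = sample(cell_labels(), n_left, replace = TRUE)),
    right = cell_set("roi1", source[2],
                     runif(n_right, 0, extent), runif(n_right, 0, extent),
                     label = sample(cell_labels(), n_right, replace = TRUE))
  )
}

# Literal evaluation of the four kappa definitions from a 4x4 count matrix
# (classes 1..3 plus missing in row/col 4), written as explicit loops.
oracle_kappas <- function(m) {
  stopifnot(all(dim(m) == c(4, 4)), m[4, 4] == 0)
  N <- sum(m)
  row_m <- rowSums(m); col_m <- colSums(m)
  core_diag <- m[1, 1] + m[2, 2] + m[3, 3]
  core_total <- sum(m[1:3, 1:3])

  k <- function(po, pe) (po - pe) / (1 - pe)

  # standard on the 3x3 core
  std_row <- rowSums(m[1:3, 1:3]); std_col <- colSums(m[1:3, 1:3])
  po_std <- core_diag / core_total
  pe_std <- sum(std_row * std_col) / core_total^2

  po_rc <- (core_diag + m[4, 4]) / N
  pe_rc <- (sum(row_m[1:3] * col_m[1:3]) + row_m[4] * col_m[4]) / N^2

  po_lw <- core_diag / core_total
  pe_lw <- sum((row_m[1:3] - m[1:3, 4]) * (col_m[1:3] - m[4, 1:3])) / core_total^2

  po_gw <- core_diag / core_total
  pe_gw <- sum(row_m[1:3] * col_m[1:3]) / ((N - row_m[4]) * (N - col_m[4]))

  list(
    standard = list(po = po_std, pe = pe_std, kappa = k(po_std, pe_std)),
    regular_category = list(po = po_rc, pe = pe_rc, kappa = k(po_rc, pe_rc)),
    listwise_deletion = list(po = po_lw, pe = pe_lw, kappa = k(po_lw, pe_lw)),
    gwet = list(po = po_gw, pe = pe_gw, kappa = k(po_gw, pe_gw))
  )
}

# Random extended confusion counts with nonempty core and zero (t, t) cell.
random_ecm_counts <- function(max_count = 40) {
  repeat {
    m <- matrix(rpois(16, max_count / 4), 4, 4)
    m[4, 4] <- 0
    if (sum(m[1:3, 1:3]) > 0 && sum(m) > 0) return(m)
  }
}

expect_kappa_equal <- function(res, oracle) {
  expect_equal(res$po, oracle$po, tolerance = 1e-12)
  expect_equal(res$pe, oracle$pe, tolerance = 1e-12)
  expect_equal(res$kappa, oracle$kappa, tolerance = 1e-12)
}
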