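test_that("standard kappa reproduces hand-evaluated cases", {
  r <- kappa_standard(diag(c(10, 10, 10)))
  expect_equal(r$po, 1)
  expect_equal(r$pe, 1 / 3)
  expect_equal(r$kappa, 1)
  expect_equal(r$interpretation, "almost_perfect")

  r <- kappa_standard(matrix(4, 3, 3))
  expect_equal(r$po, 1 / 3)
  expect_equal(r$pe, 1 / 3)
  expect_equal(r$kappa, 0)

  m <- rbind(c(20, 5, 0), c(5, 20, 5), c(0, 5, 40))
  # direct evaluation: Po = 80/100, Pe = (25*25 + 30*30 + 45*45)/100^2
  r <- kappa_standard(m)
  expect_equal(r$po, 0.8)
  expect_equal(r$pe, (25 * 25 + 30 * 30 + 45 * 45) / 1e4)
  expect_equal(r$kappa, (0.8 - 0.355) / (1 - 0.355))
})

test_that("all four variants match the formula oracle on random matrices", {
  set.seed(31)
  for (rep in 1:40) {
    m <- random_ecm_counts()
    ecm <- extended_confusion(m)
    oracle <- oracle_kappas(m)
    expect_kappa_equal(kappa_standard(m[1:3, 1:3]), oracle$standard)
    expect_kappa_equal(kappa_regular_category(ecm), oracle$regular_category)
    expect_kappa_equal(kappa_listwise_deletion(ecm), oracle$listwise_deletion)
    expect_kappa_equal(kappa_gwet(ecm), oracle$gwet)
  }
})

test_that("variants collapse to standard kappa without missingness", {
  set.seed(5)
  for (rep in 1:20) {
    m <- matrix(0L, 4, 4)
    m[1:3, 1:3] <- rpois(9, 12)
    if (sum(m[1:3, 1:3]) == 0 || sum(diag(m)[1:3]) == sum(m)) next
    ecm <- extended_confusion(m)
    std <- kappa_standard(m[1:3, 1:3])
    for (f in list(kappa_regular_category, kappa_listwise_deletion, kappa_gwet)) {
      v <- f(ecm)
      expect_equal(v$kappa, std$kappa, tolerance = 1e-12)
      expect_equal(v$po, std$po, tolerance = 1e-12)
      expect_equal(v$pe, std$pe, tolerance = 1e-12)
    }
  }
})

test_that("omissions penalize Regular Category but not Listwise/Gwet Po", {
  base <- matrix(0L, 4, 4)
  diag(base)[1:3] <- 10L
  full <- extended_confusion(base)
  with_miss <- base
  with_miss[1:3, 4] <- c(4L, 3L, 3L)  # 10 cells missed by rater B
  miss <- extended_confusion(with_miss)

  expect_equal(kappa_regular_category(full)$kappa, 1)
  expect_lt(kappa_regular_category(miss)$kappa, 1)
  # raters almost perfectly agree on jointly labeled cells
  expect_equal(kappa_listwise_deletion(miss)$po, 1)
  expect_equal(kappa_listwise_deletion(miss)$kappa, 1)
  expect_equal(kappa_gwet(miss)$po, 1)
})

test_that("one-sided missingness leaves Gwet Po fixed and moves only Pe", {
  m <- matrix(0L, 4, 4)
  m[1:3, 1:3] <- rbind(c(12L, 2L, 1L), c(2L, 9L, 1L), c(0L, 1L, 15L))
  g0 <- kappa_gwet(extended_confusion(m))
  m2 <- m; m2[1:3, 4] <- c(5L, 2L, 2L)
  g1 <- kappa_gwet(extended_confusion(m2))
  expect_equal(g1$po, g0$po)
  expect_false(isTRUE(all.equal(g1$pe, g0$pe)))
})

test_that("undefined statistics raise errors rather than returning zero", {
  expect_error(kappa_standard(matrix(0, 3, 3)), "undefined")
  empty_core <- matrix(0L, 4, 4); empty_core[1, 4] <- 5L
  expect_error(kappa_listwise_deletion(extended_confusion(empty_core)),
               "both raters")
  expect_error(kappa_gwet(extended_confusion(empty_core)), "both raters")
  one_class <- matrix(0L, 3, 3); one_class[1, 1] <- 10L
  expect_error(kappa_standard(one_class), "Pe = 1")
})

test_that("Landis-Koch interpretation follows the interval table", {
  expect_equal(
    interpret_kappa(c(-0.1, 0, 0.1, 0.2, 0.3, 0.5, 0.7, 0.9, 1.0)),
    c("poor", "slight", "slight", "slight", "fair", "moderate",
      "substantial", "almost_perfect", "almost_perfect")
  )
  # monotone in kappa
  ks <- sort(runif(50, -0.5, 1))
  lvls <- c("poor", "slight", "fair", "moderate", "substantial", "almost_perfect")
  codes <- match(interpret_kappa(ks), lvls)
  expect_true(all(diff(codes) >= 0))
})

test_that("Po and Pe stay within [0, 1] on random valid inputs", {
  set.seed(77)
  for (rep in 1:30) {
    ecm <- extended_confusion(random_ecm_counts())
    for (f in list(kappa_regular_category, kappa_listwise_deletion, kappa_gwet)) {
      r <- tryCatch(f(ecm), error = function(e) NULL)
      if (is.null(r)) next
      expect_gte(r$po, 0); expect_lte(r$po, 1)
      expect_gte(r$pe, 0); expect_lte(r$pe, 1)
      expect_lte(r$kappa, 1)
    }
  }
})

test_that("pairwise report covers all pairs and pools over ROIs", {
  truth1 <- generate_layout(n_cells = 150, roi_id = "roi1", seed = 1)
  truth2 <- generate_layout(n_cells = 150, roi_id = "roi2", seed = 2)
  raters <- purrr::map(c(A = 11, B = 12, C = 13), function(s) {
    dplyr::bind_rows(
      simulate_rater(truth1, source_id = paste0("r", s), seed = s)$cells,
      simulate_rater(truth2, source_id = paste0("r", s), seed = s + 100)$cells
    )
  })
  pooled <- pairwise_agreement_report(raters, pooled = TRUE)
  expect_equal(nrow(pooled), 3 * 4)  # 3 pairs x 4 variants
  per_roi <- pairwise_agreement_report(raters, pooled = FALSE)
  expect_equal(sort(unique(per_roi$roi_id)), c("roi1", "roi2"))
  expect_equal(nrow(per_roi), 2 * 3 * 4)

  # identical raters agree perfectly under every variant
  same <- lapply(c("a", "b", "c"), function(id)
    dplyr::mutate(truth1, source_id = id))
  all_one <- pairwise_agreement_report(same)
  expect_true(all(all_one$kappa == 1))
})

test_that("simulated raters show the omission-dominated kappa ordering", {
  truth <- generate_layout(n_cells = 600, seed = 21)
  raters <- purrr::map(1:3, function(i) {
    simulate_rater(truth, miss_prob = 0.15, jitter_sd = 2,
                   confusion = label_confusion(0.97),
                   source_id = paste0("r", i), seed = 30 + i)$cells
  })
  rep <- pairwise_agreement_report(raters)
  wide <- tidyr::pivot_wider(rep[, c("left_source", "right_source",
                                     "variant", "kappa")],
                             names_from = "variant", values_from = "kappa")
  expect_true(all(wide$regular_category < wide$listwise_deletion))
  expect_true(all(wide$listwise_deletion > 0.8))
})
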