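test_that("offset enumeration gives the 13 canonical directions", {
  offs <- glcm_offsets()
  expect_equal(nrow(offs), 13L)
  has <- function(d) any(apply(offs, 1, function(o) all(o == d)))
  expect_true(has(c(1, 0, 0)))
  expect_true(has(c(0, 1, 0)))
  expect_true(has(c(0, 0, 1)))
  expect_false(has(c(-1, 0, 0)))     # antipodal representative excluded
  # no antipodal pair and canonical sign
  for (i in seq_len(nrow(offs))) {
    expect_false(has(-offs[i, ]))
    expect_gt(offs[i, which(offs[i, ] != 0)[1]], 0)
  }
})

test_that("quantization uses equal-width bins on the ROI range", {
  q1 <- with(list(v = make_volume(c(0, 99), c(2, 1, 1))),
             quantize_roi(v, full_mask(c(2, 1, 1)), 2))
  expect_equal(as.vector(q1$labels), c(1L, 2L))

  q2 <- quantize_roi(make_volume(c(0, 49.9, 50, 100), c(4, 1, 1)),
                     full_mask(c(4, 1, 1)), 2)
  expect_equal(as.vector(q2$labels), c(1L, 1L, 2L, 2L))

  q3 <- quantize_roi(make_volume(rep(7, 8), c(2, 2, 2)),
                     full_mask(c(2, 2, 2)), 25)
  expect_true(all(q3$labels == 1L))

  expect_error(quantize_roi(make_volume(1:4, c(4, 1, 1)),
                            full_mask(c(4, 1, 1)), 1), "levels")
})

test_that("co-occurrence counting matches brute-force enumeration", {
  lab <- array(NA_integer_, c(2, 2, 1))
  lab[, , 1] <- rbind(c(1L, 2L), c(1L, 2L))
  q <- as_quantized(lab, 2)

  g <- compute_glcm(q, c(0, 1, 0), symmetrize = TRUE)
  expect_equal(g$P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  g2 <- compute_glcm(q, c(0, 1, 0), symmetrize = FALSE)
  expect_equal(g2$P, matrix(c(0, 0, 1, 0), 2, 2))

  const <- as_quantized(array(1L, c(3, 3, 3)), 4)
  g3 <- compute_glcm(const, c(1, 0, 0))
  expect_equal(g3$P[1, 1], 1)
  expect_equal(sum(g3$P), 1)

  expect_error(compute_glcm(q, c(0, 0, 5)), "no valid pairs")
})

test_that("the 2x2 worked example evaluates every feature correctly", {
  P <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  f <- glcm_features(as_glcm(P))
  expected <- c(
    "Mean" = 1.5, "Variance" = 0.25, "Energy" = 0.5, "Entropy" = log(2),
    "Contrast" = 1, "Correlation" = -1, "Dissimilarity" = 1,
    "Homogeneity" = 0.5, "Diff average" = 1, "Diff variance" = 0,
    "Diff entropy" = 0, "Sum average" = 3, "Sum variance" = 0,
    "Sum entropy" = 0, "Angular 2nd moment" = 0.5
  )
  for (nm in names(expected))
    expect_equal(unname(f[nm]), unname(expected[nm]), tolerance = 1e-9,
                 label = nm)
})

test_that("degenerate and uniform matrices follow the stated policies", {
  # single-cell distribution (constant ROI)
  P1 <- matrix(0, 3, 3); P1[1, 1] <- 1
  f1 <- glcm_features(as_glcm(P1))
  expect_equal(unname(f1["Contrast"]), 0)
  expect_equal(unname(f1["Homogeneity"]), 1)
  expect_equal(unname(f1["Energy"]), 1)
  expect_equal(unname(f1["Entropy"]), 0)
  expect_equal(unname(f1["Correlation"]), 0)                 # zero-sigma policy
  expect_equal(unname(f1["Information correlation A"]), 0)   # zero-denominator
  expect_equal(unname(f1["Sum average"]), 2)                 # 1-based indices

  # uniform over all L^2 cells
  L <- 4
  fU <- glcm_features(as_glcm(matrix(1 / L^2, L, L)))
  expect_equal(unname(fU["Energy"]), 1 / L^2, tolerance = 1e-12)
  expect_equal(unname(fU["Entropy"]), 2 * log(L), tolerance = 1e-12)
  expect_equal(unname(fU["Information correlation B"]), 0, tolerance = 1e-9)
  expect_equal(unname(fU["Maximal correlation coefficient"]), 0,
               tolerance = 1e-9)

  expect_error(glcm_feature(as_glcm(P1), "NotAFeature"), "unknown")
})

test_that("direction aggregation returns mean and range", {
  expect_equal(aggregate_directions(rep(3.5, 13)),
               c(mean = 3.5, range = 0))
  expect_equal(aggregate_directions((1:13) / 13),
               c(mean = 7 / 13, range = 12 / 13), tolerance = 1e-12)
  expect_warning(one <- aggregate_directions(2.5), "single")
  expect_equal(one, c(mean = 2.5, range = 0))
  expect_error(aggregate_directions(numeric(0)), "excluded")
})

test_that("extract_features emits the full battery", {
  r <- random_roi(7, max_dim = 6)
  ft <- extract_features(r$volume, r$mask, levels = c(25, 32))
  expect_equal(nrow(ft), 80L)
  expect_setequal(unique(ft$family),
                  c("Histogram", "GLCM(25) mean", "GLCM(25) range",
                    "GLCM(32) mean", "GLCM(32) range"))
  expect_equal(sum(ft$family == "Histogram"), 8L)
  expect_equal(sum(grepl("^GLCM\\(25\\)", ft$family)), 36L)
  expect_equal(sum(grepl("^GLCM\\(32\\)", ft$family)), 36L)

  ft25 <- extract_features(r$volume, r$mask, levels = 25)
  expect_equal(nrow(ft25), 44L)

  expect_error(
    extract_features(r$volume, roi_mask(array(FALSE, r$volume$shape))),
    "empty")
})

test_that("energy equals angular 2nd moment and range >= 0 everywhere", {
  r <- random_roi(21, max_dim = 6)
  ft <- extract_features(r$volume, r$mask)
  glcm <- ft[ft$family != "Histogram", ]
  for (fam in unique(glcm$family)) {
    sub <- glcm[glcm$family == fam, ]
    expect_equal(sub$value[sub$feature == "Energy"],
                 sub$value[sub$feature == "Angular 2nd moment"],
                 tolerance = 1e-12)
  }
  expect_true(all(glcm$value[grepl("range", glcm$family)] >= -1e-12))
})

test_that("GLCM invariants hold on random ROIs", {
  offs <- glcm_offsets()
  for (seed in 1:15) {
    r <- random_roi(seed + 100, max_dim = 6)
    L <- sample(3:8, 1)
    q <- quantize_roi(r$volume, r$mask, L)
    o <- offs[sample(13, 1), ]
    g <- tryCatch(compute_glcm(q, o), error = function(e) NULL)
    if (is.null(g)) next
    expect_equal(sum(g$P), 1, tolerance = 1e-9)
    expect_equal(g$P, t(g$P))                       # symmetrized
    f <- glcm_features(g)
    expect_true(f["Correlation"] >= -1 - 1e-9 && f["Correlation"] <= 1 + 1e-9)
    expect_gt(f["Homogeneity"], 0); expect_lte(f["Homogeneity"], 1 + 1e-12)
    expect_gt(f["Energy"], 0); expect_lte(f["Energy"], 1 + 1e-12)
    expect_gte(f["Contrast"], 0)
    expect_gte(f["Diff variance"], -1e-12)
    expect_gte(f["Sum variance"], -1e-12)
    expect_gte(f["Sum average"], 2 - 1e-12)
    expect_lte(f["Sum average"], 2 * L + 1e-12)
    # symmetrization implies equal marginals
    expect_equal(rowSums(g$P), colSums(g$P), tolerance = 1e-12)
  }
})

test_that("features are invariant under strictly increasing intensity maps", {
  for (seed in 1:5) {
    r <- random_roi(seed + 200, max_dim = 5)
    affine <- volume_grid(3.7 * r$volume$values + 120, r$volume$spacing)
    offs <- glcm_offsets()
    q1 <- quantize_roi(r$volume, r$mask, 6)
    q2 <- quantize_roi(affine, r$mask, 6)
    expect_identical(q1$labels, q2$labels)
    for (k in c(1, 7, 13)) {
      g1 <- tryCatch(compute_glcm(q1, offs[k, ]), error = function(e) NULL)
      if (is.null(g1)) next
      g2 <- compute_glcm(q2, offs[k, ])
      expect_equal(glcm_features(g1), glcm_features(g2), tolerance = 1e-12)
    }
  }
})

test_that("MCC of an independent distribution is zero", {
  set.seed(31)
  for (i in 1:5) {
    L <- sample(3:8, 1)
    px <- runif(L); px <- px / sum(px)
    py <- runif(L); py <- py / sum(py)
    f <- glcm_features(as_glcm(outer(px, py), symmetrize = FALSE))
    expect_equal(unname(f["Maximal correlation coefficient"]), 0,
                 tolerance = 1e-8)
  }
})

test_that("features match the pair-enumeration oracle on small ROIs", {
  offs <- glcm_offsets()
  for (seed in 1:20) {
    r <- random_roi(seed + 300, max_dim = 6)
    L <- sample(3:8, 1)
    q <- quantize_roi(r$volume, r$mask, L)
    o <- offs[sample(13, 1), ]
    sym <- seed %% 2 == 0
    g <- tryCatch(compute_glcm(q, o, symmetrize = sym),
                  error = function(e) NULL)
    if (is.null(g)) next
    P_oracle <- oracle_glcm_P(q$labels, o, L, symmetrize = sym)
    expect_equal(g$P, P_oracle, tolerance = 1e-12)
    expect_equal(glcm_features(g), oracle_glcm_features(P_oracle),
                 tolerance = 1e-9)
  }
})
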