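test_that("Q reproduces hand-computed ratios", {
  # cond - ref differences {1, -1}; repeat differences {0.5, -0.5} -> Q = 2
  expect_equal(q_measure(c(0, 0), c(1, -1), cbind(c(0, 0), c(-0.5, 0.5))), 2)
  # identical condition values -> Q = 0
  expect_equal(q_measure(c(3, 7, 1), c(3, 7, 1), cbind(c(1, 2), c(1.4, 2.7))), 0)
  # numerator sample equal to denominator sample -> Q = 1
  expect_equal(q_measure(c(0, 0), c(0.5, -0.5), cbind(c(0.5, -0.5), c(0, 0))), 1)
})

test_that("Q validates its inputs and degenerate spreads", {
  expect_error(q_measure(1, 1, cbind(1:2, 2:3)), "N >= 2")
  expect_error(q_measure(1:3, 1:2, cbind(1:2, 2:3)), "pair up")
  expect_error(q_measure(1:2, 2:3, cbind(c(1, 2), c(1, 2))),
               "zero repeatability")
  expect_error(q_measure(1:2, 2:3, matrix(1:2, 1, 2)), "M x 2")
})

test_that("Q is invariant to affine rescaling and case permutation", {
  set.seed(8)
  for (i in 1:10) {
    ref <- rnorm(20); cond <- ref + rnorm(20, 0, 0.5)
    rep2 <- cbind(rnorm(10), rnorm(10))
    q <- q_measure(ref, cond, rep2)
    expect_equal(q_measure(5 * ref, 5 * cond, 5 * rep2), q, tolerance = 1e-12)
    expect_equal(q_measure(ref + 3, cond + 3, rep2 + 3), q, tolerance = 1e-12)
    p <- sample(20)
    expect_equal(q_measure(ref[p], cond[p], rep2), q, tolerance = 1e-12)
  }
})

test_that("Q recovers an engineered noise ratio", {
  set.seed(12)
  for (ratio in c(0.5, 2)) {
    qs <- vapply(1:100, function(i) {
      f0 <- rnorm(33)
      fr <- f0 + rnorm(33, 0, ratio)
      rep2 <- cbind(f0[1:17], f0[1:17] + rnorm(17, 0, 1))
      q_measure(f0, fr, rep2)
    }, 0)
    expect_lt(abs(median(qs) - ratio) / ratio, 0.15)
  }
})

make_features <- function(values_by_condition, feature = "F1",
                          family = "Histogram", repeats = NULL) {
  out <- do.call(rbind, lapply(names(values_by_condition), function(cond) {
    v <- values_by_condition[[cond]]
    data.frame(case_id = paste0("c", seq_along(v)), condition = cond,
               contour_id = 1L, family = family, feature = feature,
               value = v, stringsAsFactors = FALSE)
  }))
  if (!is.null(repeats)) {
    out <- rbind(out, data.frame(
      case_id = paste0("c", seq_along(repeats)), condition = names(values_by_condition)[1],
      contour_id = 2L, family = family, feature = feature,
      value = repeats, stringsAsFactors = FALSE))
  }
  out
}

test_that("q_table uses all cases in the numerator and repeat pairs in the denominator", {
  ref <- c(0, 1, 2, 3)
  feats <- make_features(list(REF = ref, A = ref + c(1, -1, 1, -1)),
                         repeats = ref[1:3] + c(0.5, -0.5, 0.5))
  qt <- q_table(feats, "REF")
  expect_s3_class(qt, "q_table")
  expect_equal(nrow(qt), 1L)
  expect_equal(attr(qt, "N"), 4L)
  expect_equal(attr(qt, "M"), 3L)
  den <- sd(c(-0.5, 0.5, -0.5))
  num <- sd(c(1, -1, 1, -1))
  expect_equal(qt$Q[qt$condition == "A"], num / den, tolerance = 1e-12)

  # zero-repeatability feature excluded, not infinite
  feats2 <- make_features(list(REF = ref, A = ref + 1), repeats = ref[1:3])
  qt2 <- q_table(feats2, "REF")
  expect_true(is.na(qt2$Q))
  expect_match(attr(qt2, "zero_denominator"), "F1")
  expect_error(q_table(feats, "nope"), "not present")
})

test_that("condition summaries compute per-condition mean and sd", {
  feats <- make_features(list(REF = c(1, 2, 3), A = c(2, 2, 2)))
  s <- condition_feature_summary(feats)
  expect_equal(s$mean[s$condition == "REF"], 2)
  expect_equal(s$sd[s$condition == "REF"], 1)
  expect_equal(s$sd[s$condition == "A"], 0)
  single <- make_features(list(REF = 1, A = 2))
  expect_error(condition_feature_summary(single), "insufficient")
})

test_that("nearest-condition matching picks the closest mean with tie rule", {
  s <- data.frame(family = "Histogram", feature = "Mean",
                  condition = c("REF", "A", "B"),
                  n = 5, mean = c(10, 9.5, 12), sd = 1,
                  stringsAsFactors = FALSE)
  expect_equal(nearest_condition(s, "Histogram", "Mean", "REF"), "A")

  s2 <- s; s2$mean <- c(0, 1, -1)
  expect_warning(pick <- nearest_condition(s2, "Histogram", "Mean", "REF"),
                 "tie")
  expect_equal(pick, "A")

  s3 <- s[s$condition != "B", ]
  expect_equal(nearest_condition(s3, "Histogram", "Mean", "REF"), "A")
  expect_error(nearest_condition(s[s$condition != "REF", ],
                                 "Histogram", "Mean", "REF"), "reference")
})

test_that("nearest-condition histogram conserves the feature count", {
  # engineered: GLCM features sit nearest a noisier condition, histogram
  # features nearest a smoother one -> two modes
  rows <- list()
  for (i in 1:8) rows[[length(rows) + 1]] <-
    data.frame(family = "Histogram", feature = paste0("h", i),
               condition = c("REF", "smooth", "noisy"),
               n = 5, mean = c(0, 0.1, 5), sd = 1)
  for (i in 1:20) rows[[length(rows) + 1]] <-
    data.frame(family = "GLCM(25) mean", feature = paste0("g", i),
               condition = c("REF", "smooth", "noisy"),
               n = 5, mean = c(1, 6, 1.2), sd = 1)
  s <- do.call(rbind, rows)
  h <- nearest_condition_histogram(s, "REF")
  expect_equal(sum(h$count), 28)
  expect_equal(h$count[h$condition == "smooth"], 8)
  expect_equal(h$count[h$condition == "noisy"], 20)
})

test_that("feature ranking follows count then descending max Q", {
  qt <- rbind(
    data.frame(family = "Histogram", feature = "X",
               condition = paste0("c", 1:12), Q = c(rep(0.5, 11), 1.2)),
    data.frame(family = "Histogram", feature = "Y",
               condition = paste0("c", 1:12), Q = c(rep(0.5, 9), 1.62, 1.3, 1.1)),
    data.frame(family = "Histogram", feature = "Z",
               condition = paste0("c", 1:12), Q = c(rep(0.5, 9), 1.54, 1.2, 1.1))
  )
  class(qt) <- c("q_table", "data.frame")
  r <- rank_features(qt)
  expect_equal(r$feature, c("X", "Y", "Z"))   # count 11 > 9; then max 1.62 > 1.54
  expect_equal(r$rank, 1:3)
  expect_equal(r$n_q_le_1, c(11, 9, 9))
  expect_equal(r$max_condition[2], "c10")

  # all-identical stats: stable order by label
  qt2 <- data.frame(family = "F", feature = c("b", "a", "c"),
                    condition = "c1", Q = 0.5)
  class(qt2) <- c("q_table", "data.frame")
  expect_equal(rank_features(qt2)$feature, c("a", "b", "c"))

  # restriction to one feature returns exactly that feature
  r1 <- rank_features(qt[qt$feature == "Y", ])
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$feature, "Y")
})

test_that("condition ranking counts per family and sorts by total", {
  qt <- expand.grid(feature = paste0("f", 1:80), condition = c("A", "B", "C"),
                    stringsAsFactors = FALSE)
  qt$family <- rep(c("Histogram", "GLCM(25) mean"), length.out = nrow(qt))
  set.seed(2)
  qt$Q <- 2
  qt$Q[qt$condition == "A"][1:76] <- 0.5
  qt$Q[qt$condition == "B"][1:63] <- 0.5
  qt$Q[qt$condition == "C"][1] <- 0.5
  class(qt) <- c("q_table", "data.frame")
  r <- rank_conditions(qt)
  expect_equal(r$condition, c("A", "B", "C"))
  expect_equal(r$n_q_le_1, c(76, 63, 1))
  famcols <- grep("^n_le_1 ", names(r))
  expect_equal(rowSums(r[, famcols]), r$n_q_le_1, ignore_attr = TRUE)
})

test_that("analyze_robustness assembles a coherent object", {
  set.seed(42)
  conds <- c("REF", "A", "B")
  rows <- list()
  for (feat in c("Mean", "Entropy")) for (cond in conds) {
    noise <- if (feat == "Mean") 0.01 else 1
    base <- rnorm(10)
    rows[[length(rows) + 1]] <- data.frame(
      case_id = paste0("c", 1:10), condition = cond, contour_id = 1L,
      family = "Histogram", feature = feat,
      value = base + if (cond == "REF") 0 else rnorm(10, 0, noise))
  }
  for (feat in c("Mean", "Entropy")) rows[[length(rows) + 1]] <-
    data.frame(case_id = paste0("c", 1:5), condition = "REF", contour_id = 2L,
               family = "Histogram", feature = feat, value = rnorm(5, 0, 0.1))
  feats <- do.call(rbind, rows)
  res <- analyze_robustness(feats, "REF")
  expect_s3_class(res, "feature_robustness")
  expect_equal(res$N, 10L)
  expect_equal(res$M, 5L)
  expect_equal(nrow(res$qtable), 2 * 2)
  expect_equal(nrow(res$feature_ranking), 2)
  expect_equal(nrow(res$condition_ranking), 2)
  expect_equal(sum(res$nearest$count), 2)
  expect_output(print(res), "feature_robustness")
})
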