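#' Reproducibility-to-repeatability ratio Q
#'
#' The stability score of a feature f under a condition change r is the ratio
#' of two spreads: the standard deviation, across cases, of the difference
#' between the feature at condition r and at the reference condition
#' (reproducibility), divided by the standard deviation, across repeat
#' contours at the reference condition, of the difference between the two
#' contours of the same case (repeatability):
#'
#' \deqn{Q(f; r) = \frac{S(f_r(\Phi_i) - f_0(\Phi_i))_{i=1..N}}
#'                     {S(f_0(\Phi_i) - f_0(\Phi_i'))_{i=1..M}}}
#'
#' Q <= 1 marks the feature as robust to the change: the condition effect is
#' within re-contouring noise.
#'
#' @param ref_values numeric, f at the reference condition per case (length N).
#' @param cond_values numeric, f at condition r per case (same cases, length N).
#' @param repeat_ref two-column matrix (or data.frame): f at the reference
#'   condition for the original and the repeat contour of the M repeat cases.
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return Scalar Q >= 0.
#' @examples
#' q_measure(c(0, 0), c(1, -1), cbind(c(0, 0), c(0.5, -0.5)))  # 2
#' @export
q_measure <- function(ref_values, cond_values, repeat_ref,
                      sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(ref_values) != length(cond_values))
    stop("ref_values and cond_values must pair up case by case")
  if (length(ref_values) < 2L) stop("need N >= 2 cases")
  repeat_ref <- as.matrix(repeat_ref)
  if (ncol(repeat_ref) != 2L || nrow(repeat_ref) < 2L)
    stop("repeat_ref must be an M x 2 matrix with M >= 2")
  S <- function(x) {
    if (sd_type == "sample") sd(x) else sqrt(mean((x - mean(x))^2))
  }
  den <- S(repeat_ref[, 1] - repeat_ref[, 2])
  if (!is.finite(den) || den == 0)
    stop("zero repeatability spread: Q undefined for this feature")
  S(cond_values - ref_values) / den
}

#' Q table for a long-form feature table
#'
#' Computes Q for every (feature, non-reference condition) pair of a
#' long-form feature table. The numerator uses all cases with the feature at
#' both the reference and the target condition (contour `1`); the denominator
#' uses the cases carrying a repeat contour (contour `2`) at the reference
#' condition only. Features whose repeatability spread is zero get `NA`
#' entries and are listed in the `zero_denominator` attribute rather than
#' reported as infinite.
#'
#' @param features data.frame with columns `case_id`, `condition`,
#'   `contour_id`, `family`, `feature`, `value` (see [extract_features()] and
#'   [extract_study()]).
#' @param reference reference condition label.
#' @param sd_type passed to [q_measure()].
#' @return A data.frame of class `q_table` with columns `family`, `feature`,
#'   `condition`, `Q`; attributes `reference`, `N`, `M`, `zero_denominator`.
#' @export
q_table <- function(features, reference, sd_type = "sample") {
  need <- c("case_id", "condition", "contour_id", "family", "feature", "value")
  if (!all(need %in% names(features)))
    stop("features must have columns: ", paste(need, collapse = ", "))
  conds <- unique(features$condition)
  if (!reference %in% conds)
    stop("reference condition '", reference, "' not present")
  others <- setdiff(conds, reference)
  keyf <- function(d) paste(d$family, d$feature, sep = "\r")
  prim <- features[features$contour_id == 1L, ]
  rep2 <- features[features$contour_id == 2L & features$condition == reference, ]
  ref1 <- prim[prim$condition == reference, ]

  feats <- unique(prim[, c("family", "feature")])
  zero_den <- character()
  out <- vector("list", nrow(feats) * length(others))
  idx <- 0L
  for (fi in seq_len(nrow(feats))) {
    fam <- feats$family[fi]; fea <- feats$feature[fi]
    r0 <- ref1[ref1$family == fam & ref1$feature == fea, ]
    p2 <- rep2[rep2$family == fam & rep2$feature == fea, ]
    pair_cases <- intersect(r0$case_id, p2$case_id)
    den_ok <- length(pair_cases) >= 2L
    if (den_ok) {
      a <- r0$value[match(pair_cases, r0$case_id)]
      b <- p2$value[match(pair_cases, p2$case_id)]
      S <- if (sd_type == "sample") sd(a - b) else sqrt(mean(((a - b) - mean(a - b))^2))
      den_ok <- is.finite(S) && S > 0
    }
    if (!den_ok)
      zero_den <- c(zero_den, paste(fam, fea, sep = " / "))
    for (cond in others) {
      rc <- prim[prim$condition == cond & prim$family == fam &
                   prim$feature == fea, ]
      cases <- intersect(r0$case_id, rc$case_id)
      idx <- idx + 1L
      qv <- NA_real_
      if (den_ok && length(cases) >= 2L) {
        qv <- q_measure(r0$value[match(cases, r0$case_id)],
                        rc$value[match(cases, rc$case_id)],
                        cbind(a, b), sd_type = sd_type)
      }
      out[[idx]] <- data.frame(family = fam, feature = fea, condition = cond,
                               Q = qv, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "reference") <- reference
  attr(res, "N") <- length(unique(prim$case_id))
  attr(res, "M") <- length(unique(rep2$case_id))
  attr(res, "zero_denominator") <- unique(zero_den)
  class(res) <- c("q_table", "data.frame")
  res
}

#' Per-condition feature summaries
#'
#' Mean and standard deviation of each feature across ROIs/cases, per
#' condition — the data layer behind per-condition feature plots and
#' nearest-condition matching.
#'
#' @param features long-form feature table (primary contours are used).
#' @return data.frame with columns `family`, `feature`, `condition`, `n`,
#'   `mean`, `sd`.
#' @export
condition_feature_summary <- function(features) {
  prim <- features[features$contour_id == 1L, , drop = FALSE]
  if (nrow(prim) == 0L) prim <- features
  key <- interaction(prim$family, prim$feature, prim$condition, drop = TRUE)
  n <- tapply(prim$value, key, length)
  if (any(n < 2L)) {
    bad <- names(n)[n < 2L]
    stop("insufficient observations (< 2) for: ",
         paste(head(bad, 5L), collapse = "; "),
         if (length(bad) > 5L) " ..." else "")
  }
  mu <- tapply(prim$value, key, mean)
  sdev <- tapply(prim$value, key, sd)
  # interaction() labels are ambiguous; rebuild keys from first occurrences
  first <- prim[!duplicated(key), c("family", "feature", "condition")]
  ord <- match(names(mu), as.character(key[!duplicated(key)]))
  out <- data.frame(first[ord, ], n = as.integer(n), mean = as.numeric(mu),
                    sd = as.numeric(sdev), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Nearest condition for one feature
#'
#' The non-reference condition whose mean feature value lies closest to the
#' reference condition's mean. Ties are broken by condition label order with
#' a warning.
#'
#' @param summary output of [condition_feature_summary()].
#' @param family,feature feature identity.
#' @param reference reference condition label.
#' @return Condition label.
#' @export
nearest_condition <- function(summary, family, feature, reference) {
  s <- summary[summary$family == family & summary$feature == feature, ]
  if (!reference %in% s$condition)
    stop("reference condition '", reference, "' missing for ",
         family, " / ", feature)
  ref_mean <- s$mean[s$condition == reference]
  s <- s[s$condition != reference, ]
  if (nrow(s) == 0L) stop("no non-reference condition for ", feature)
  d <- abs(s$mean - ref_mean)
  best <- which(d <= min(d) + 0)
  if (length(best) > 1L) {
    best <- best[order(s$condition[best])]
    warning("nearest-condition tie for ", family, " / ", feature,
            "; first by label order chosen")
  }
  s$condition[best[1L]]
}

#' Nearest-condition frequency histogram
#'
#' For every feature, finds the condition nearest in mean value to the
#' reference and tabulates how often each condition is selected. Counts sum
#' to the number of features.
#'
#' @param summary output of [condition_feature_summary()].
#' @param reference reference condition label.
#' @return data.frame with columns `condition` and `count` (all non-reference
#'   conditions, zero counts included).
#' @export
nearest_condition_histogram <- function(summary, reference) {
  feats <- unique(summary[, c("family", "feature")])
  conds <- setdiff(unique(summary$condition), reference)
  picks <- vapply(seq_len(nrow(feats)), function(i)
    suppressWarnings(
      nearest_condition(summary, feats$family[i], feats$feature[i], reference)),
    "")
  counts <- table(factor(picks, levels = sort(conds)))
  data.frame(condition = names(counts), count = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Rank features by robustness
#'
#' Features are ranked by the number of conditions with Q <= 1 (descending),
#' ties broken by max Q descending — the empirically consistent tie order of
#' the study tables, counterintuitive as it reads — then by feature label.
#' Features with only `NA` Q entries (zero repeatability spread) are excluded
#' and listed in the `excluded` attribute.
#'
#' @param qtable a [q_table()].
#' @return data.frame with columns `rank`, `family`, `feature`, `mean_q`,
#'   `sd_q`, `min_q`, `max_q`, `n_q_le_1`, `max_condition`.
#' @export
rank_features <- function(qtable) {
  qt <- qtable[!is.na(qtable$Q), , drop = FALSE]
  key <- paste(qt$family, qt$feature, sep = "\r")
  all_key <- unique(paste(qtable$family, qtable$feature, sep = "\r"))
  excluded <- setdiff(all_key, unique(key))
  split_q <- split(seq_len(nrow(qt)), key)
  rows <- lapply(split_q, function(ix) {
    q <- qt$Q[ix]
    data.frame(
      family = qt$family[ix[1]], feature = qt$feature[ix[1]],
      mean_q = mean(q), sd_q = sd(q), min_q = min(q), max_q = max(q),
      n_q_le_1 = sum(q <= 1),
      max_condition = qt$condition[ix[which.max(q)]],
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  label <- paste(res$family, res$feature)
  ord <- order(-res$n_q_le_1, -res$max_q, label)
  res <- res[ord, ]
  res <- cbind(rank = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  attr(res, "excluded") <- gsub("\r", " / ", excluded)
  res
}

#' Rank conditions by how many features stay robust
#'
#' Conditions are ranked by the number of features with Q <= 1 (descending),
#' ties broken by max Q descending, then label. Per-family counts accompany
#' the total.
#'
#' @param qtable a [q_table()].
#' @return data.frame with columns `rank`, `condition`, `mean_q`, `sd_q`,
#'   `min_q`, `max_q`, `n_q_le_1`, then one `n_le_1 <family>` column per
#'   feature family.
#' @export
rank_conditions <- function(qtable) {
  qt <- qtable[!is.na(qtable$Q), , drop = FALSE]
  fams <- unique(qtable$family)
  split_q <- split(seq_len(nrow(qt)), qt$condition)
  rows <- lapply(names(split_q), function(cond) {
    ix <- split_q[[cond]]
    q <- qt$Q[ix]
    base <- data.frame(
      condition = cond, mean_q = mean(q), sd_q = sd(q),
      min_q = min(q), max_q = max(q), n_q_le_1 = sum(q <= 1),
      stringsAsFactors = FALSE
    )
    for (fam in fams)
      base[[paste0("n_le_1 ", fam)]] <- sum(q[qt$family[ix] == fam] <= 1)
    base
  })
  res <- do.call(rbind, rows)
  ord <- order(-res$n_q_le_1, -res$max_q, res$condition)
  res <- res[ord, ]
  res <- cbind(rank = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Robustness analysis of a feature table
#'
#' The analysis stage in one call: builds the Q table against the reference
#' condition, ranks features and conditions, computes per-condition
#' summaries and the nearest-condition histogram.
#'
#' @param features long-form feature table (see [q_table()] for the required
#'   columns).
#' @param reference reference condition label.
#' @param sd_type standard-deviation convention for Q, see [q_measure()].
#' @return An object of class `feature_robustness`: list with `qtable`,
#'   `feature_ranking`, `condition_ranking`, `summary`, `nearest`,
#'   `reference`, `N`, `M`.
#' @export
analyze_robustness <- function(features, reference, sd_type = "sample") {
  qt <- q_table(features, reference, sd_type = sd_type)
  summ <- condition_feature_summary(features)
  structure(
    list(
      qtable = qt,
      feature_ranking = rank_features(qt),
      condition_ranking = rank_conditions(qt),
      summary = summ,
      nearest = nearest_condition_histogram(summ, reference),
      reference = reference,
      N = attr(qt, "N"),
      M = attr(qt, "M")
    ),
    class = "feature_robustness"
  )
}

#' @export
print.feature_robustness <- function(x, ...) {
  cat("<feature_robustness> reference condition: ", x$reference,
      "  (N = ", x$N, " cases, M = ", x$M, " repeat contours)\n", sep = "")
  nf <- nrow(x$feature_ranking)
  cat("  ", nf, " features x ", length(unique(x$qtable$condition)),
      " non-reference conditions\n", sep = "")
  cat("  most robust features:\n")
  print(head(x$feature_ranking[, c("rank", "family", "feature", "n_q_le_1",
                                   "max_q")], 5L), row.names = FALSE)
  cat("  condition ranking (top/bottom):\n")
  cr <- x$condition_ranking[, c("rank", "condition", "n_q_le_1", "max_q")]
  print(head(cr, 2L), row.names = FALSE)
  print(tail(cr, 2L), row.names = FALSE)
  invisible(x)
}

#' @export
summary.feature_robustness <- function(object, ...) {
  q <- object$qtable$Q
  cat("Q statistic over ", sum(!is.na(q)), " (feature, condition) pairs\n",
      sep = "")
  print(summary(q))
  cat("features with Q <= 1 everywhere: ",
      sum(object$feature_ranking$n_q_le_1 ==
            length(unique(object$qtable$condition))), "\n", sep = "")
  zd <- attr(object$qtable, "zero_denominator")
  if (length(zd)) cat("zero-repeatability features excluded: ",
                      paste(zd, collapse = "; "), "\n", sep = "")
  invisible(object)
}

#' @param x a `feature_robustness` object.
#' @param which `"q"` for per-feature Q profiles, `"nearest"` for the
#'   nearest-condition histogram.
#' @param ... ignored.
#' @rdname analyze_robustness
#' @export
plot.feature_robustness <- function(x, which = c("q", "nearest"), ...) {
  which <- match.arg(which)
  if (which == "nearest") {
    barplot(x$nearest$count, names.arg = x$nearest$condition, las = 2,
            ylab = "# features nearest to reference",
            main = paste("Nearest condition to", x$reference))
  } else {
    qt <- x$qtable[!is.na(x$qtable$Q), ]
    key <- factor(paste(qt$family, qt$feature))
    plot(as.integer(key), qt$Q, pch = 16, cex = 0.5, xaxt = "n",
         xlab = "feature", ylab = "Q",
         main = paste("Q vs", x$reference))
    abline(h = 1, lty = 2)
  }
  invisible(x)
}
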