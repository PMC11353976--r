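# Metrics, class-imbalance handling, calibration, and the rank-based
# statistical comparisons used to contrast models and feature sets.

#' Inverse-frequency class weights
#'
#' `weight_c = N / (2 * N_c)`, which equalizes the total weighted count of the
#' two classes.
#'
#' @param labels Vector with exactly two distinct values.
#' @return Named numeric vector of per-class weights.
#' @export
class_weights <- function(labels) {
  tab <- table(labels)
  if (length(tab) != 2) abort("exactly two classes are required")
  w <- length(labels) / (2 * as.numeric(tab))
  setNames(w, names(tab))
}

# internal alias so functions with a `class_weights` argument can still call
# the exported helper
.class_weights <- class_weights

#' Downsample the majority class to a 1:1 ratio
#'
#' Uniform without-replacement subsample of the majority class to the minority
#' size; the minority class is untouched. A no-op when already balanced.
#'
#' @param features Wide feature tibble.
#' @param labels 0/1 outcome aligned with rows.
#' @param seed Integer seed.
#' @return List with `features`, `labels`, and the kept row `indices`.
#' @export
downsample_majority <- function(features, labels, seed = 1L) {
  tab <- table(labels)
  if (length(tab) < 2 || tab[1] == tab[2]) {
    return(list(features = features, labels = labels,
                indices = seq_along(labels)))
  }
  minority <- names(tab)[which.min(tab)]
  maj_idx <- which(labels != minority)
  keep_maj <- with_seed(seed, sample(maj_idx, min(tab)))
  idx <- sort(c(which(labels == minority), keep_maj))
  list(features = features[idx, , drop = FALSE], labels = labels[idx],
       indices = idx)
}

#' Binary classification metrics
#'
#' AUROC as tie-corrected concordance (rank formula), AUPRC as the step
#' integral of the precision-recall curve, and F1/precision/recall at the
#' given score threshold.
#'
#' @param scores Positive-class scores.
#' @param labels 0/1 outcomes; both classes must be present (ranking metrics
#'   are undefined otherwise and an error is raised).
#' @param threshold Classification threshold (default 0.5).
#' @return One-row tibble (auroc, auprc, f1, precision, recall).
#' @export
binary_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    abort("both classes must be present for ranking metrics")
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  auroc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  last <- cumsum(rle(s)$lengths)          # indices closing each threshold
  tp <- cumsum(y)[last]
  fp <- (seq_along(y) - cumsum(y))[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  auprc <- sum(diff(c(0, rec)) * prec)

  pred <- as.integer(scores >= threshold)
  tp2 <- sum(pred == 1 & labels == 1)
  precision <- if (sum(pred) == 0) 0 else tp2 / sum(pred)
  recall <- tp2 / n1
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble(auroc = auroc, auprc = auprc, f1 = f1,
         precision = precision, recall = recall)
}

#' Platt calibration of classifier scores
#'
#' Fits `p = 1 / (1 + exp(A * s + B))` by logistic-loss minimization on the
#' training scores (a logistic regression of the labels on the scores).
#'
#' @param scores Training scores.
#' @param labels Training 0/1 labels (both classes required).
#' @return An object of class `platt_scaling` with coefficients `A`, `B`;
#'   apply with [calibrate()].
#' @export
platt_calibrate <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort("both classes must be present")
  if (length(unique(scores)) < 2) {
    warn("degenerate (constant) scores; calibration reduces to the base rate")
    b0 <- qlogis(mean(labels))
    fit <- list(A = 0, B = -b0)
  } else {
    g <- glm(labels ~ scores, family = binomial())
    fit <- list(A = -unname(coef(g)[2]), B = -unname(coef(g)[1]))
  }
  structure(fit, class = "platt_scaling")
}

#' Apply a fitted Platt transform
#'
#' @param fit A `platt_scaling`.
#' @param scores Scores to calibrate.
#' @return Calibrated probabilities.
#' @export
calibrate <- function(fit, scores) {
  stopifnot(inherits(fit, "platt_scaling"))
  1 / (1 + exp(fit$A * scores + fit$B))
}

#' Reliability curve over uniform probability bins
#'
#' Groups predictions into `n_bins` equal-width bins on \[0, 1\] (empty bins
#' omitted) and contrasts the mean predicted probability with the empirical
#' positive rate per bin.
#'
#' @param probs Predicted probabilities in \[0, 1\].
#' @param labels 0/1 outcomes.
#' @param n_bins Number of bins (default 10).
#' @return Tibble (bin, mean_prob, frac_pos, n).
#' @export
reliability_bins <- function(probs, labels, n_bins = 10L) {
  stopifnot(all(probs >= 0 & probs <= 1))
  b <- pmin(n_bins, pmax(1L, ceiling(probs * n_bins)))
  b[probs == 0] <- 1L
  tibble(bin = b, prob = probs, label = as.integer(labels)) %>%
    group_by(.data$bin) %>%
    summarise(mean_prob = mean(.data$prob), frac_pos = mean(.data$label),
              n = n(), .groups = "drop") %>%
    arrange(.data$bin)
}

#' Plot a reliability curve
#'
#' @param probs,labels,n_bins As in [reliability_bins()].
#' @return A ggplot with the identity line of perfect calibration.
#' @export
plot_reliability <- function(probs, labels, n_bins = 10L) {
  df <- reliability_bins(probs, labels, n_bins)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_prob, y = .data$frac_pos)) +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::geom_line() + ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "mean predicted probability",
                  y = "observed positive fraction", size = "bin size")
}

#' Friedman omnibus test with Nemenyi post hoc comparisons
#'
#' Ranks treatments within each block (average ranks on ties), computes the
#' tie-corrected Friedman chi-square, and, when significant at `alpha`
#' (default 0.01, a Bonferroni-corrected 0.05 over five metrics), all-pairs
#' Nemenyi p-values from the studentized-range distribution.
#'
#' @param metrics Numeric matrix or data frame, blocks (e.g. CV folds) by
#'   treatments (e.g. models or feature sets).
#' @param alpha Significance level gating the post hoc tests.
#' @return List with `friedman` (one-row tibble), `mean_ranks`, and `nemenyi`
#'   (tibble of pairwise p-values, or `NULL` when the omnibus test is not
#'   significant).
#' @export
friedman_nemenyi <- function(metrics, alpha = 0.01) {
  M <- as.matrix(metrics)
  n <- nrow(M); k <- ncol(M)
  if (n < 2 || k < 2) abort("need at least 2 blocks and 2 treatments")
  if (any(apply(M, 1, function(r) length(unique(r)) == 1))) {
    warn("one or more blocks have all treatments tied")
  }
  R <- t(apply(M, 1, rank))
  Rj <- colSums(R)
  denom <- sum(R^2) - n * k * (k + 1)^2 / 4
  if (denom <= 0) {
    stat <- 0; p <- 1
  } else {
    stat <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / denom
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  }
  mean_ranks <- setNames(Rj / n, colnames(M) %||% paste0("T", seq_len(k)))
  friedman <- tibble(statistic = stat, df = k - 1, p_value = p,
                     alpha = alpha, significant = p < alpha)
  nemenyi <- NULL
  if (friedman$significant) {
    se <- sqrt(k * (k + 1) / (6 * n))
    pairs <- utils::combn(seq_len(k), 2)
    nemenyi <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      q <- abs(mean_ranks[i1] - mean_ranks[i2]) / se
      tibble(treatment_1 = names(mean_ranks)[i1],
             treatment_2 = names(mean_ranks)[i2],
             mean_rank_diff = unname(mean_ranks[i1] - mean_ranks[i2]),
             p_value = ptukey(q * sqrt(2), nmeans = k, df = Inf,
                              lower.tail = FALSE))
    })
  }
  list(friedman = friedman, mean_ranks = mean_ranks, nemenyi = nemenyi)
}

#' Kendall rank concordance of importance rankings
#'
#' Pairwise tie-corrected Kendall tau-b between columns of an importance
#' table, on a \[-1, 1\] scale.
#'
#' @param rankings Numeric matrix or data frame, features by
#'   replicates/models.
#' @return Symmetric correlation matrix.
#' @export
kendall_concordance <- function(rankings) {
  M <- as.matrix(rankings)
  if (nrow(M) < 2) abort("need at least 2 features")
  cor(M, method = "kendall")
}

#' Plot a Kendall concordance matrix
#'
#' @param mat Output of [kendall_concordance()].
#' @return A ggplot heatmap.
#' @export
plot_concordance <- function(mat) {
  df <- as_tibble(as.data.frame(as.table(mat)))
  names(df) <- c("a", "b", "tau")
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$tau)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Kendall tau-b")
}

#' Permutation feature importance
#'
#' Model-agnostic importance: the mean drop in AUROC over `n_repeats` seeded
#' shuffles of each feature column.
#'
#' @param fitted A fitted classifier (see [fit_classifier()]).
#' @param features Wide feature tibble.
#' @param labels 0/1 outcomes.
#' @param n_repeats Shuffles per feature (default 10).
#' @param seed Integer seed.
#' @return Tibble (feature, importance).
#' @export
permutation_importance <- function(fitted, features, labels, n_repeats = 10L,
                                   seed = 1L) {
  base <- binary_metrics(predict_scores(fitted, features), labels)$auroc
  feats <- setdiff(names(features), "patient_id")
  set.seed(seed)
  drops <- purrr::map_dbl(feats, function(f) {
    mean(purrr::map_dbl(seq_len(n_repeats), function(i) {
      perm <- features
      perm[[f]] <- sample(perm[[f]])
      base - binary_metrics(predict_scores(fitted, perm), labels)$auroc
    }))
  })
  tibble(feature = feats, importance = drops) %>%
    arrange(dplyr::desc(.data$importance))
}
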