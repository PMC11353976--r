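# Minimum-redundancy maximum-relevance (mRMR) feature selection with
# random-forest relevance and Pearson-correlation redundancy, a feature-count
# scan, and post-selection k-nearest-neighbour imputation (train-fitted).

fm_matrix <- function(fm) {
  as.matrix(fm[, setdiff(names(fm), "patient_id"), drop = FALSE])
}

# Relevance: impurity importance of a seeded reference forest; missing values
# are median-imputed for this computation only (selection precedes the kNN
# imputation of the retained features). Columns are put in lexicographic
# order before fitting so the result does not depend on column order.
rf_relevance <- function(X, labels, seed, num_trees = 500L) {
  Xi <- apply(X[, order(colnames(X)), drop = FALSE], 2, function(col) {
    med <- median(col, na.rm = TRUE)
    if (is.na(med)) med <- 0
    col[is.na(col)] <- med
    col
  })
  rf <- ranger::ranger(x = as.data.frame(Xi), y = factor(labels),
                       importance = "impurity", num.trees = num_trees,
                       seed = seed)
  imp <- rf$variable.importance
  imp[colnames(X)]
}

#' Greedy mRMR feature selection
#'
#' Relevance is the impurity importance of a seeded random forest (computed
#' once); redundancy of a candidate is the mean absolute Pearson correlation
#' with the already-selected features. The first pick maximizes relevance;
#' each later step maximizes `relevance / max(redundancy, 1e-6)`. Ties are
#' broken lexicographically by feature name. Zero-variance features get
#' redundancy contribution 0 (with a warning).
#'
#' @param features Wide feature tibble (`patient_id` + feature columns).
#' @param labels 0/1 outcome aligned with rows.
#' @param k Number of features to select.
#' @param seed Integer seed for the relevance forest.
#' @return An object of class `selection_result`: tibble (step, feature,
#'   relevance, redundancy, score).
#' @export
mrmr_select <- function(features, labels, k, seed = 1L) {
  if (anyNA(labels)) abort("missing labels are not allowed")
  X <- fm_matrix(features)
  if (k > ncol(X)) abort("`k` exceeds the number of features")
  v <- apply(X, 2, var, na.rm = TRUE)
  if (any(v == 0, na.rm = TRUE)) {
    warn("zero-variance features present; their redundancy is taken as 0")
  }
  rel <- rf_relevance(X, labels, seed)
  cm <- suppressWarnings(abs(cor(X, use = "pairwise.complete.obs")))
  cm[!is.finite(cm)] <- 0
  nms <- colnames(X)
  selected <- character(0)
  rows <- vector("list", k)
  for (step in seq_len(k)) {
    cand <- setdiff(nms, selected)
    if (step == 1) {
      red <- setNames(rep(NA_real_, length(cand)), cand)
      score <- rel[cand]
    } else {
      red <- colMeans(cm[selected, cand, drop = FALSE])
      score <- rel[cand] / pmax(red, 1e-6)
    }
    ord <- order(-score, cand)
    pick <- cand[ord[1]]
    rows[[step]] <- tibble(step = step, feature = pick,
                           relevance = unname(rel[pick]),
                           redundancy = unname(red[pick]),
                           score = unname(score[pick]))
    selected <- c(selected, pick)
  }
  out <- bind_rows(rows)
  class(out) <- c("selection_result", class(out))
  out
}

#' Scan the number of selected features
#'
#' Selects increasing feature counts by mRMR (the greedy order is nested, so
#' larger selections extend smaller ones) and, for each count, fits
#' `replicates` seeded random forests on a stratified split and reports
#' held-out metrics.
#'
#' @param features,labels As in [mrmr_select()].
#' @param grid Ascending feature counts to evaluate.
#' @param seed Integer seed.
#' @param replicates Reference-model replicates per count (default 3).
#' @param val_fraction Held-out fraction (default 0.3).
#' @return Tibble (k, replicate, auroc, auprc, f1, precision, recall).
#' @export
scan_feature_counts <- function(features, labels, grid, seed = 1L,
                                replicates = 3L, val_fraction = 0.3) {
  if (is.unsorted(grid)) abort("`grid` must be ascending")
  if (max(grid) > ncol(fm_matrix(features))) {
    abort("`grid` exceeds the feature count")
  }
  sel <- mrmr_select(features, labels, k = max(grid), seed = seed)
  Xall <- fm_matrix(features)
  rows <- list()
  for (k in grid) {
    feats <- sel$feature[seq_len(k)]
    for (rep_i in seq_len(replicates)) {
      s <- seed + 97L * rep_i + k
      fold <- stratified_folds(labels, k = round(1 / val_fraction), seed = s)
      hold <- fold == 1L
      tr <- knn_impute(features[!hold, c("patient_id", feats)],
                       features[!hold, c("patient_id", feats)])
      va <- knn_impute(features[!hold, c("patient_id", feats)],
                       features[hold, c("patient_id", feats)])
      rf <- ranger::ranger(x = as.data.frame(fm_matrix(tr)),
                           y = factor(labels[!hold]), probability = TRUE,
                           num.trees = 300L, seed = s)
      sc <- predict(rf, as.data.frame(fm_matrix(va)))$predictions[, "1"]
      met <- binary_metrics(sc, labels[hold])
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(k = k, replicate = rep_i), met)
    }
  }
  bind_rows(rows)
}

#' k-nearest-neighbour imputation fit on the training rows
#'
#' Each missing entry is replaced by the mean of that feature over the
#' `k_neighbors` nearest training rows in which the feature is observed;
#' distance is Euclidean over mutually observed features (normalized by the
#' number of such features). Training statistics are never updated from the
#' data being imputed; observed entries are never altered.
#'
#' @param train Wide feature tibble the imputer is fit on.
#' @param newdata Tibble to impute (defaults to `train`).
#' @param k_neighbors Donor count (default 5).
#' @return `newdata` with missing entries filled.
#' @export
knn_impute <- function(train, newdata = train, k_neighbors = 5L) {
  Xt <- fm_matrix(train)
  Xn <- fm_matrix(newdata)
  if (!identical(colnames(Xt), colnames(Xn))) {
    abort("`train` and `newdata` must share feature columns")
  }
  if (any(rowSums(!is.na(Xn)) == 0)) abort("a row has all features missing")
  if (!any(is.na(Xn))) return(newdata)
  Wt <- !is.na(Xt); Wn <- !is.na(Xn)
  Mt <- Xt; Mt[!Wt] <- 0
  Mn <- Xn; Mn[!Wn] <- 0
  # squared distance over mutual support, averaged per observed coordinate
  D2 <- (Mn^2) %*% t(Wt) + Wn %*% t(Mt^2) - 2 * Mn %*% t(Mt)
  cnt <- Wn %*% t(Wt)
  D <- D2 / cnt
  D[cnt == 0] <- Inf
  out <- Xn
  miss_rows <- which(rowSums(!Wn) > 0)
  for (i in miss_rows) {
    ord <- order(D[i, ])
    for (f in which(!Wn[i, ])) {
      donors <- ord[Wt[ord, f]]
      donors <- donors[is.finite(D[i, donors])]
      if (length(donors) == 0) {
        out[i, f] <- mean(Xt[, f], na.rm = TRUE)
        next
      }
      use <- donors[seq_len(min(k_neighbors, length(donors)))]
      out[i, f] <- mean(Xt[use, f])
    }
  }
  res <- newdata
  res[, colnames(out)] <- as_tibble(out)
  res
}
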