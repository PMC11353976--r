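# Pluggable classifier contract. Every model is wrapped behind the same
# surface: fit(features, labels, seed, params) honouring class weights or
# majority downsampling, predict_scores() returning positive-class scores in
# [0, 1], and importances() returning per-feature scores (or NULL when the
# model offers none). Models whose optional backing package is unavailable
# are simply absent from `available_classifiers()`.

#' Construct a classifier specification
#'
#' @param name One of `"dt"` (decision tree, rpart), `"lr"` (L2-penalized
#'   logistic regression, glmnet), `"rf"` (random forest, ranger), `"xgb"`
#'   (gradient boosting, xgboost; uses majority downsampling instead of class
#'   weights), `"tgfnn"` (the in-package fuzzy-rule network).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("rf", "lr", "dt", "xgb", "tgfnn")) {
  name <- match.arg(name)
  if (name == "xgb" && !requireNamespace("xgboost", quietly = TRUE)) {
    abort("the xgboost package is not installed")
  }
  imbalance <- if (name == "xgb") "downsample" else "weights"
  structure(list(name = name, imbalance = imbalance),
            class = "classifier_spec")
}

#' Names of the classifiers available in this session
#' @return Character vector.
#' @export
available_classifiers <- function() {
  base <- c("rf", "lr", "dt", "tgfnn")
  if (requireNamespace("xgboost", quietly = TRUE)) c(base, "xgb") else base
}

#' Fit a classifier behind the pluggable contract
#'
#' Class imbalance is handled per model: inverse-frequency class weights
#' where the backend supports them, otherwise seeded downsampling of the
#' majority class to 1:1.
#'
#' @param spec A [classifier_spec()] (or a model name).
#' @param features Wide feature tibble (`patient_id` + numeric columns, no
#'   missing values).
#' @param labels 0/1 outcomes.
#' @param seed Integer seed.
#' @param params Named list of hyperparameters (see [default_grid()]).
#' @return An object of class `fitted_classifier`.
#' @export
fit_classifier <- function(spec, features, labels, seed = 1L,
                           params = list()) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort("single-class training data")
  if (spec$imbalance == "downsample") {
    ds <- downsample_majority(features, labels, seed = seed)
    features <- ds$features; labels <- ds$labels
    w <- rep(1, length(labels))
  } else {
    cw <- class_weights(labels)
    w <- unname(cw[as.character(labels)])
  }
  X <- fm_matrix(features)
  y <- factor(labels, levels = c(0, 1))
  model <- switch(
    spec$name,
    dt = {
      p <- utils::modifyList(list(cp = 0.01, maxdepth = 10L, minsplit = 20L),
                             params)
      Xs <- as.data.frame(X)
      names(Xs) <- paste0("X", seq_len(ncol(X)))   # rpart-safe names
      Xs$y <- y
      with_seed(seed, rpart::rpart(
        y ~ ., data = Xs, weights = w, method = "class",
        control = rpart::rpart.control(cp = p$cp, maxdepth = p$maxdepth,
                                       minsplit = p$minsplit)))
    },
    lr = {
      p <- utils::modifyList(list(lambda = 0.01), params)
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = p$lambda, weights = w, standardize = TRUE)
    },
    rf = {
      p <- utils::modifyList(list(num_trees = 300L, mtry_frac = NULL,
                                  min_node_size = 10L), params)
      mtry <- if (is.null(p$mtry_frac)) NULL else
        max(1L, floor(p$mtry_frac * ncol(X)))
      ranger::ranger(x = as.data.frame(X), y = y, probability = TRUE,
                     num.trees = p$num_trees, mtry = mtry,
                     min.node.size = p$min_node_size, case.weights = w,
                     importance = "impurity", seed = seed)
    },
    xgb = {
      p <- utils::modifyList(list(nrounds = 100L, eta = 0.1, max_depth = 4L,
                                  subsample = 0.9), params)
      dtrain <- xgboost::xgb.DMatrix(X, label = labels)
      with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = p$eta,
                      max_depth = p$max_depth, subsample = p$subsample,
                      nthread = 1),
        data = dtrain, nrounds = p$nrounds, verbose = 0))
    },
    tgfnn = {
      cw <- class_weights(labels)
      do.call(fit_tgfnn, c(list(features = features, labels = labels,
                                class_weights = cw, seed = seed), params))
    }
  )
  structure(list(spec = spec, model = model,
                 feature_names = colnames(X)),
            class = "fitted_classifier")
}

#' Positive-class scores of a fitted classifier
#'
#' @param fitted A `fitted_classifier`.
#' @param features Wide feature tibble.
#' @return Numeric scores in \[0, 1\].
#' @export
predict_scores <- function(fitted, features) {
  X <- fm_matrix(features)[, fitted$feature_names, drop = FALSE]
  m <- fitted$model
  switch(
    fitted$spec$name,
    dt = {
      Xs <- as.data.frame(X)
      names(Xs) <- paste0("X", seq_len(ncol(X)))
      unname(predict(m, Xs)[, "1"])
    },
    lr = drop(predict(m, newx = X, type = "response")),
    rf = predict(m, as.data.frame(X))$predictions[, "1"],
    xgb = predict(m, xgboost::xgb.DMatrix(X)),
    tgfnn = predict(m, features)[, "1"]
  )
}

#' Per-feature importance scores of a fitted classifier
#'
#' @param fitted A `fitted_classifier`.
#' @return Tibble (feature, importance); logistic coefficients are signed,
#'   tree importances non-negative.
#' @export
importances <- function(fitted) {
  m <- fitted$model
  imp <- switch(
    fitted$spec$name,
    dt = {
      safe <- paste0("X", seq_along(fitted$feature_names))
      v <- m$variable.importance
      setNames(unname(v[safe]), fitted$feature_names)
    },
    lr = {
      cf <- as.matrix(coef(m))[, 1]
      setNames(unname(cf[fitted$feature_names]), fitted$feature_names)
    },
    rf = m$variable.importance[fitted$feature_names],
    xgb = {
      tb <- xgboost::xgb.importance(model = m)
      setNames(tb$Gain[match(fitted$feature_names, tb$Feature)],
               fitted$feature_names)
    },
    tgfnn = tgfnn_variable_importance(m)
  )
  if (is.null(names(imp))) names(imp) <- fitted$feature_names
  imp[is.na(imp)] <- 0
  tibble(feature = names(imp), importance = unname(imp))
}

#' Default random-search grids
#'
#' Each entry is a function drawing one value for the hyperparameter.
#'
#' @param name Classifier name.
#' @return Named list of sampler functions.
#' @export
default_grid <- function(name) {
  switch(
    name,
    dt = list(cp = function() 10^runif(1, -4, -1),
              maxdepth = function() sample(2:15, 1),
              minsplit = function() sample(c(5L, 10L, 20L, 40L), 1)),
    lr = list(lambda = function() 10^runif(1, -4, 1)),
    rf = list(num_trees = function() sample(c(100L, 200L, 300L, 500L), 1),
              mtry_frac = function() runif(1, 0.1, 0.9),
              min_node_size = function() sample(c(1L, 5L, 10L, 20L), 1)),
    xgb = list(nrounds = function() sample(c(50L, 100L, 200L), 1),
               eta = function() 10^runif(1, -2, -0.3),
               max_depth = function() sample(2:8, 1),
               subsample = function() runif(1, 0.6, 1)),
    tgfnn = list(n_rules = function() sample(c(4L, 8L, 12L), 1),
                 learning_rate = function() 10^runif(1, -2.5, -1),
                 epochs = function() sample(c(150L, 300L), 1))
  )
}

#' Random hyperparameter search by cross-validated F1
#'
#' Draws `n_draws` hyperparameter combinations and scores each by the mean
#' validation F1 across `folds` stratified folds; the best combination is
#' returned (ties keep the first drawn).
#'
#' @param spec A [classifier_spec()] or name.
#' @param grid Named list of sampler functions (default [default_grid()]).
#' @param n_draws Number of sampled combinations.
#' @param features,labels Training data.
#' @param folds Stratified folds (default 3).
#' @param seed Integer seed.
#' @return List with `best_params`, `best_f1`, and the search `trace`.
#' @export
random_search <- function(spec, grid = NULL, n_draws = 20L, features, labels,
                          folds = 3L, seed = 1L) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  grid <- grid %||% default_grid(spec$name)
  if (length(grid) == 0) abort("empty hyperparameter grid")
  labels <- as.integer(labels)
  fold_id <- stratified_folds(labels, folds, seed = seed)
  draws <- with_seed(seed + 1L, purrr::map(seq_len(n_draws), function(i) {
    purrr::map(grid, function(s) if (is.function(s)) s() else sample(s, 1))
  }))
  trace <- purrr::map_dfr(seq_len(n_draws), function(i) {
    f1s <- purrr::map_dbl(seq_len(folds), function(fd) {
      tr <- fold_id != fd
      fit <- fit_classifier(spec, features[tr, , drop = FALSE], labels[tr],
                            seed = seed + fd, params = draws[[i]])
      sc <- predict_scores(fit, features[!tr, , drop = FALSE])
      binary_metrics(sc, labels[!tr])$f1
    })
    tibble(draw = i, mean_f1 = mean(f1s))
  })
  best <- which.max(trace$mean_f1)    # strict max: ties keep the first drawn
  list(best_params = draws[[best]], best_f1 = trace$mean_f1[best],
       trace = trace)
}

#' Cross-validated evaluation against a fixed test set
#'
#' Five-fold (by default) stratified cross-validation: each fold's model is
#' evaluated on its own training folds, its validation fold, and the fixed
#' test set, giving a mean and spread for every metric.
#'
#' @param spec A [classifier_spec()] or name.
#' @param params Tuned hyperparameters.
#' @param train_features,train_labels Training split.
#' @param test_features,test_labels Fixed test split.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return A `cv_result` tibble (fold, split, auroc, auprc, f1, precision,
#'   recall); summarize with [glance()].
#' @export
kfold_evaluate <- function(spec, params = list(), train_features,
                           train_labels, test_features, test_labels,
                           folds = 5L, seed = 1L) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  train_labels <- as.integer(train_labels)
  fold_id <- stratified_folds(train_labels, folds, seed = seed)
  out <- purrr::map_dfr(seq_len(folds), function(fd) {
    tr <- fold_id != fd
    if (length(unique(train_labels[!tr])) < 2) {
      abort("a validation fold contains a single class")
    }
    fit <- fit_classifier(spec, train_features[tr, , drop = FALSE],
                          train_labels[tr], seed = seed + fd, params = params)
    evaluate_on <- function(split, feats, labs) {
      dplyr::bind_cols(tibble(fold = fd, split = split),
                       binary_metrics(predict_scores(fit, feats), labs))
    }
    bind_rows(
      evaluate_on("train", train_features[tr, , drop = FALSE],
                  train_labels[tr]),
      evaluate_on("validation", train_features[!tr, , drop = FALSE],
                  train_labels[!tr]),
      evaluate_on("test", test_features, test_labels)
    )
  })
  class(out) <- c("cv_result", class(out))
  attr(out, "model") <- spec$name
  out
}

#' Mean and SD of cross-validated metrics per split
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble (split, metric, mean, sd).
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(c("auroc", "auprc", "f1", "precision", "recall"),
                        names_to = "metric") %>%
    group_by(.data$split, .data$metric) %>%
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              .groups = "drop")
}
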