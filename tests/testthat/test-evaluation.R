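test_that("class weights equalize the weighted class totals", {
  expect_equal(unname(class_weights(rep(c(0, 1), each = 50))), c(1, 1))
  w <- class_weights(c(rep(0, 100), rep(1, 50)))
  expect_equal(unname(w), c(0.75, 1.5))
  expect_equal(w[["0"]] * 100, w[["1"]] * 50)
  expect_error(class_weights(rep(1, 5)), "two classes")
})

test_that("majority downsampling reaches 1:1 deterministically", {
  set.seed(1)
  feats <- tibble::tibble(patient_id = sprintf("P%03d", 1:300),
                          x = rnorm(300))
  labels <- c(rep(0, 200), rep(1, 100))
  ds <- downsample_majority(feats, labels, seed = 5)
  expect_equal(as.vector(table(ds$labels)), c(100L, 100L))
  expect_true(all(which(labels == 1) %in% ds$indices))
  ds2 <- downsample_majority(feats, labels, seed = 5)
  expect_identical(ds$indices, ds2$indices)
  bal <- downsample_majority(feats[1:200, ], rep(c(0, 1), 100), seed = 1)
  expect_equal(length(bal$labels), 200)
})

test_that("AUROC and AUPRC equal brute-force oracles, ties included", {
  m <- binary_metrics(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))
  expect_equal(m$auroc, 0.75)
  perf <- binary_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perf$auroc, 1)
  expect_equal(perf$auprc, 1)
  expect_equal(perf$f1, 1)
  set.seed(7)
  for (i in 1:10) {
    n <- sample(20:100, 1)
    scores <- round(runif(n), 2)          # rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    m <- binary_metrics(scores, labels)
    expect_equal(m$auroc, auroc_oracle(scores, labels), tolerance = 1e-9)
    expect_equal(m$auprc, auprc_oracle(scores, labels), tolerance = 1e-9)
  }
  # random scores on a large sample sit near 0.5
  set.seed(8)
  big <- binary_metrics(runif(4000), rbinom(4000, 1, 0.5))
  expect_lt(abs(big$auroc - 0.5), 3 / sqrt(4000))
  expect_error(binary_metrics(runif(5), rep(1, 5)), "both classes")
})

test_that("threshold metrics behave at the 0.5 default", {
  m <- binary_metrics(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0))
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)
  none <- binary_metrics(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1))
  expect_equal(none$precision, 0)
  expect_equal(none$f1, 0)
})

test_that("Platt scaling matches a dense grid-search oracle on a toy set", {
  scores <- c(0.1, 0.2, 0.4, 0.6, 0.8, 0.9)
  labels <- c(0, 0, 1, 0, 1, 1)
  fit <- platt_calibrate(scores, labels)
  oracle <- platt_grid_oracle(scores, labels, a_range = c(-30, 0),
                              b_range = c(-5, 15), steps = 300)
  expect_lt(abs(log_loss(calibrate(fit, scores), labels) - oracle$loss), 1e-3)
  # flipping the labels negates the ordering of the transform
  flip <- platt_calibrate(scores, 1 - labels)
  expect_equal(flip$A, -fit$A, tolerance = 1e-6)
  expect_warning(platt_calibrate(rep(0.5, 6), labels), "degenerate")
})

test_that("calibrating a logistic simulation yields a tight reliability curve", {
  set.seed(3)
  n <- 2000
  true_p <- plogis(rnorm(n, 0, 1.5))
  labels <- rbinom(n, 1, true_p)
  fit <- platt_calibrate(true_p, labels)
  cal <- calibrate(fit, true_p)
  # reliability slope of calibrated probabilities near 1
  slope <- coef(glm(labels ~ qlogis(pmin(pmax(cal, 1e-6), 1 - 1e-6)),
                    family = binomial()))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
  rb <- reliability_bins(cal, labels)
  expect_lte(nrow(rb), 10)
  expect_lt(max(abs(rb$mean_prob - rb$frac_pos)), 0.08)
})

test_that("reliability bins are uniform with empty bins omitted", {
  rb <- reliability_bins(c(0.05, 0.08, 0.95), c(0, 1, 1))
  expect_equal(nrow(rb), 2)
  expect_equal(rb$n, c(2, 1))
  expect_equal(rb$bin, c(1, 10))
  one <- reliability_bins(rep(0.55, 8), rbinom(8, 1, 0.5))
  expect_equal(nrow(one), 1)
  expect_equal(formals(reliability_bins)$n_bins, 10L)
})

test_that("the Friedman statistic equals the explicit rank-formula oracle", {
  M <- matrix(c(0.60, 0.62, 0.58,
                0.55, 0.65, 0.50,
                0.70, 0.72, 0.69,
                0.40, 0.45, 0.38), 4, 3, byrow = TRUE)
  colnames(M) <- c("a", "b", "c")
  res <- friedman_nemenyi(M, alpha = 0.01)
  expect_equal(res$friedman$statistic, friedman_oracle(M), tolerance = 1e-12)
  expect_equal(res$friedman$statistic,
               unname(stats::friedman.test(M)$statistic), tolerance = 1e-12)
  # identical treatments: statistic 0, p 1, no post hoc
  same <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3)
  expect_warning(r0 <- friedman_nemenyi(same), "tied")
  expect_equal(r0$friedman$statistic, 0)
  expect_equal(r0$friedman$p_value, 1)
  expect_null(r0$nemenyi)
  # column permutation leaves the p-value unchanged
  res_perm <- friedman_nemenyi(M[, c(3, 1, 2)], alpha = 0.01)
  expect_equal(res_perm$friedman$p_value, res$friedman$p_value)
  expect_error(friedman_nemenyi(M[1, , drop = FALSE]), "blocks")
})

test_that("Nemenyi post hoc p-values use the studentized range", {
  set.seed(2)
  # strongly separated treatments so the omnibus test is significant
  M <- cbind(a = rnorm(12, 0.2, 0.01), b = rnorm(12, 0.5, 0.01),
             c = rnorm(12, 0.8, 0.01))
  res <- friedman_nemenyi(M, alpha = 0.01)
  expect_true(res$friedman$significant)
  expect_equal(nrow(res$nemenyi), 3)
  ab <- res$nemenyi[res$nemenyi$treatment_1 == "a" &
                      res$nemenyi$treatment_2 == "b", ]
  q <- abs(diff(res$mean_ranks[c("a", "b")])) /
    sqrt(3 * 4 / (6 * 12))
  expect_equal(unname(ab$p_value),
               unname(stats::ptukey(q * sqrt(2), 3, Inf, lower.tail = FALSE)),
               tolerance = 1e-12)
  expect_true(all(res$nemenyi$p_value >= 0 & res$nemenyi$p_value <= 1))
})

test_that("Kendall concordance matches explicit pair counting", {
  r1 <- c(1, 2, 3, 4, 5)
  K <- kendall_concordance(cbind(a = r1, b = r1, c = rev(r1)))
  expect_equal(unname(K["a", "b"]), 1)
  expect_equal(unname(K["a", "c"]), -1)
  set.seed(4)
  x <- sample(10); y <- sample(10); z <- round(runif(10), 1)  # z has ties
  K2 <- kendall_concordance(cbind(x = x, y = y, z = z))
  expect_equal(unname(K2["x", "y"]), kendall_oracle(x, y), tolerance = 1e-9)
  expect_equal(unname(K2["x", "z"]), kendall_oracle(x, z), tolerance = 1e-9)
  expect_error(kendall_concordance(matrix(1, 1, 2)), "features")
})

test_that("permutation importance isolates the informative feature", {
  set.seed(9)
  n <- 400
  feats <- tibble::tibble(patient_id = sprintf("P%03d", 1:n),
                          signal = rnorm(n), junk1 = rnorm(n),
                          junk2 = rnorm(n))
  labels <- as.integer(feats$signal > 0)
  fit <- fit_classifier("lr", feats, labels, seed = 1,
                        params = list(lambda = 1e-3))
  imp <- permutation_importance(fit, feats, labels, n_repeats = 10, seed = 2)
  expect_equal(imp$feature[1], "signal")
  expect_gt(imp$importance[1], 10 * max(abs(imp$importance[-1])))
  expect_lt(max(abs(imp$importance[-1])), 0.05)
  imp2 <- permutation_importance(fit, feats, labels, n_repeats = 20, seed = 7)
  expect_equal(imp$importance[1], imp2$importance[1], tolerance = 0.05)
})

test_that("random search returns the dominant grid point", {
  set.seed(11)
  n <- 240
  feats <- tibble::tibble(patient_id = sprintf("P%03d", 1:n), x = rnorm(n),
                          z = rnorm(n))
  labels <- as.integer(feats$x + 0.3 * rnorm(n) > 0)
  # a 2-point lambda grid where weak regularization clearly dominates
  grid <- list(lambda = c(1e-4, 1e4))
  rs <- random_search("lr", grid = grid, n_draws = 8, features = feats,
                      labels = labels, seed = 3)
  expect_equal(rs$best_params$lambda, 1e-4)
  expect_equal(nrow(rs$trace), 8)
  one <- random_search("lr", grid = list(lambda = 0.5), n_draws = 1,
                       features = feats, labels = labels, seed = 1)
  expect_equal(one$best_params$lambda, 0.5)
  expect_equal(formals(random_search)$folds, 3L)
  expect_error(random_search("lr", grid = list(), n_draws = 1,
                             features = feats, labels = labels), "empty")
})

test_that("k-fold evaluation scores every fold on train, validation and test", {
  set.seed(13)
  n <- 300
  feats <- tibble::tibble(patient_id = sprintf("P%03d", 1:n),
                          x = rnorm(n), y = rnorm(n))
  labels <- as.integer(feats$x - feats$y > 0)    # cleanly separable
  tr <- seq_len(200)
  cv <- kfold_evaluate("lr", params = list(lambda = 1e-3),
                       train_features = feats[tr, ], train_labels = labels[tr],
                       test_features = feats[-tr, ],
                       test_labels = labels[-tr], folds = 5, seed = 2)
  expect_equal(nrow(cv), 15)
  expect_setequal(unique(cv$split), c("train", "validation", "test"))
  expect_true(all(cv$auroc[cv$split == "test"] > 0.95))
  expect_equal(formals(kfold_evaluate)$folds, 5L)
  g <- glance(cv)
  expect_equal(nrow(g), 15)      # 3 splits x 5 metrics
  expect_true(all(g$sd[g$split == "test"] >= 0))
  cv2 <- kfold_evaluate("lr", params = list(lambda = 1e-3),
                        train_features = feats[tr, ],
                        train_labels = labels[tr],
                        test_features = feats[-tr, ],
                        test_labels = labels[-tr], folds = 5, seed = 2)
  expect_identical(as.data.frame(cv), as.data.frame(cv2))
})

test_that("every bound classifier honours the fit/score/importance contract", {
  set.seed(17)
  n <- 260
  feats <- tibble::tibble(patient_id = sprintf("P%03d", 1:n),
                          a = rnorm(n), b = rnorm(n), c = rbinom(n, 1, 0.4))
  labels <- as.integer(feats$a + 0.5 * feats$c > 0)
  for (nm in intersect(available_classifiers(), c("rf", "lr", "dt", "xgb"))) {
    fit <- fit_classifier(nm, feats, labels, seed = 3)
    sc <- predict_scores(fit, feats)
    expect_length(sc, n)
    expect_true(all(is.finite(sc) & sc >= 0 & sc <= 1))
    expect_gt(binary_metrics(sc, labels)$auroc, 0.8)
    imp <- importances(fit)
    expect_setequal(imp$feature, c("a", "b", "c"))
  }
  expect_error(fit_classifier("rf", feats, rep(0, n), seed = 1),
               "single-class")
})
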