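# A hand-built fitted network: 2 rules over (x1, x2) continuous and x3
# binary; rule 1 = "x1 high AND x2 low", rule 2 = "x3 present". Raw
# parameters are the inverse transforms of the intended weights.
make_hand_tgfnn <- function(u = matrix(c(0.1, 0.1, 2, 2), 2, 2)) {
  X <- cbind(x1 = runif(10), x2 = runif(10), x3 = rbinom(10, 1, 0.5))
  cmap <- tempheno:::build_concept_map(X)
  inv_softplus <- function(y) log(expm1(y))
  alpha <- matrix(1e-9, 2, cmap$n_concepts)
  idx <- function(v, lab) which(cmap$concept_var == v &
                                  cmap$concept_label == lab)
  alpha[1, idx(1, "high")] <- 1; alpha[1, idx(2, "low")] <- 1
  alpha[1, idx(3, "present")] <- 0.5; alpha[1, idx(3, "absent")] <- 0.5
  alpha[2, idx(1, "medium")] <- 1; alpha[2, idx(2, "medium")] <- 1
  alpha[2, idx(3, "present")] <- 1
  w <- rbind(c(2, 1.5, 0.01), c(0.01, 0.01, 2))
  par <- list(mu = matrix(c(0.25, 0.5, 0.75), 3, 2),
              rho = matrix(log(0.2), 3, 2),
              Araw = log(alpha), Wraw = inv_softplus(w),
              Uraw = inv_softplus(u), b = c(0, 0),
              traw = qlogis(0.5), sraw = qlogis(0.5))
  structure(list(par = par, cmap = cmap, n_rules = 2L,
                 scaling = list(min = rep(0, 3), span = rep(1, 3)),
                 class_weights = c("0" = 1, "1" = 1), history = numeric(0),
                 best_val_f1 = NA_real_, best_epoch = 0L, seed = 1L,
                 epochs = 0L, effect = w),
            class = "tgfnn")
}

test_that("fuzzification follows the Gaussian closed form and passes binaries", {
  params <- membership_params(centers = matrix(c(0, 0.5, 1), 3, 1),
                              widths = matrix(1, 3, 1))
  x <- cbind(v = c(0, 1, 0.37))   # three distinct values: continuous
  M <- fuzzify(x, params)
  expect_equal(unname(M[1, "v.low"]), 1)          # at the low center
  expect_equal(unname(M[2, "v.low"]), exp(-1 / 2))  # one width away
  xb <- cbind(v = runif(3), b = c(0, 1, 1))
  Mb <- fuzzify(xb, membership_params(matrix(c(0.2, 0.5, 0.8), 3, 1),
                                      matrix(0.2, 3, 1)))
  expect_equal(unname(Mb[, c("b.absent", "b.present")]),
               cbind(c(1, tempheno:::EPS_M, tempheno:::EPS_M), c(tempheno:::EPS_M, 1, 1)),
               tolerance = 1e-9)
  expect_error(fuzzify(cbind(v = NaN), params), "non-finite")
  expect_error(membership_params(matrix(0, 3, 1), matrix(0, 3, 1)), "widths")
})

test_that("T-norm endpoints reproduce exact product and exact minimum", {
  set.seed(8)
  V <- 4
  M <- matrix(runif(20 * V, 0.05, 1), 20, V)
  w <- runif(V, 0.3, 2)
  mk_bank <- function(tn) rule_bank(alpha = matrix(1, 1, V), w = rbind(w),
                                    u = matrix(1, 1, 2), tnorm = tn,
                                    tconorm = 0, concept_var = 1:V)
  prod_exact <- exp((log(M) %*% w)[, 1])
  min_exact <- apply(sweep(log(M), 2, w, "*"), 1, function(z) exp(min(z)))
  expect_lt(max(abs(rule_activation(M, mk_bank(0))[, 1] - prod_exact)), 1e-9)
  expect_lt(max(abs(rule_activation(M, mk_bank(1))[, 1] - min_exact)), 1e-9)
  # worked examples: scores {0.2, 0.9} with unit weights
  M2 <- matrix(c(0.2, 0.9), 1)
  b2 <- function(tn) rule_bank(matrix(1, 1, 2), matrix(1, 1, 2),
                               matrix(1, 1, 2), tnorm = tn, tconorm = 0,
                               concept_var = 1:2)
  expect_equal(rule_activation(M2, b2(0))[1, 1], 0.18, tolerance = 1e-9)
  expect_equal(rule_activation(M2, b2(1))[1, 1], 0.2, tolerance = 1e-9)
  # all relevant memberships 1: strength 1 regardless of the parameter
  M1 <- matrix(1, 1, 2)
  for (tn in c(0, 0.3, 1)) {
    expect_equal(rule_activation(M1, b2(tn))[1, 1], 1, tolerance = 1e-9)
  }
  # weight 0 contributes neutrally
  bw0 <- rule_bank(matrix(1, 1, 2), matrix(c(1, 0), 1), matrix(1, 1, 2),
                   tnorm = 1, tconorm = 0, concept_var = 1:2)
  expect_equal(rule_activation(matrix(c(0.7, 0.05), 1), bw0)[1, 1], 0.7,
               tolerance = 1e-9)
})

test_that("T-conorm endpoints reproduce exact sum and exact maximum", {
  # two rules, class-2 importances 1; rule strengths {0.5, 0.9}
  st <- matrix(c(0.5, 0.9), 1)
  mk <- function(sn) rule_bank(alpha = matrix(1, 2, 1), w = matrix(1, 2, 1),
                               u = cbind(0, c(1, 1)), tnorm = 0, tconorm = sn,
                               concept_var = 1L)
  p_sum <- tgfnn_infer(st, mk(0))
  expect_lt(abs(p_sum[1, 2] - exp(1.4) / (exp(1.4) + 1)), 1e-9)
  p_max <- tgfnn_infer(st, mk(1))
  expect_lt(abs(p_max[1, 2] - exp(0.9) / (exp(0.9) + 1)), 1e-9)
  # zero strengths: uniform class probabilities
  expect_equal(tgfnn_infer(matrix(0, 3, 2), mk(0.4)),
               matrix(0.5, 3, 2), tolerance = 1e-12)
  expect_error(tgfnn_infer(matrix(-1, 1, 2), mk(0)), "non-negative")
})

test_that("probabilities are normalized and monotone in pure product/sum mode", {
  set.seed(12)
  for (i in 1:20) {
    V <- sample(2:5, 1); R <- sample(1:3, 1); n <- 7
    alpha <- matrix(1, R, V)
    bank <- rule_bank(alpha, matrix(runif(R * V, 0, 2), R),
                      cbind(0, runif(R, 0.2, 2)), tnorm = 0, tconorm = 0,
                      concept_var = 1:V)
    M <- matrix(runif(n * V, 0.05, 0.95), n, V)
    p <- tgfnn_infer(rule_activation(M, bank), bank)
    expect_equal(rowSums(p), rep(1, n), tolerance = 1e-12)
    j <- sample(V, 1); i0 <- sample(n, 1)
    M2 <- M; M2[i0, j] <- min(1, M[i0, j] + 0.1)
    p2 <- tgfnn_infer(rule_activation(M2, bank), bank)
    expect_gte(p2[i0, 2] + 1e-12, p[i0, 2])
  }
})

test_that("rule-bank invariants are enforced", {
  expect_error(rule_bank(matrix(c(0.5, 0.4), 1), matrix(1, 1, 1),
                         matrix(1, 1, 2), concept_var = c(1L, 1L)),
               "sum to 1")
  expect_error(rule_bank(matrix(1, 1, 1), matrix(-1, 1, 1),
                         matrix(1, 1, 2), concept_var = 1L),
               "non-negative")
  expect_error(rule_bank(matrix(1, 1, 1), matrix(1, 1, 1),
                         matrix(1, 1, 2), tnorm = 2, concept_var = 1L),
               "\\[0, 1\\]")
})

test_that("analytic gradients match finite differences", {
  set.seed(5)
  n <- 30
  X <- cbind(runif(n), runif(n), rbinom(n, 1, 0.5))
  colnames(X) <- c("a", "b", "c")
  y <- rbinom(n, 1, 0.5)
  cmap <- tempheno:::build_concept_map(X)
  par <- list(mu = matrix(runif(6), 3, 2), rho = matrix(log(0.3), 3, 2),
              Araw = matrix(rnorm(3 * cmap$n_concepts, 0, 0.5), 3),
              Wraw = matrix(rnorm(9), 3), Uraw = matrix(rnorm(6), 3),
              b = c(0.1, -0.2), traw = 0.3, sraw = -0.2)
  sw <- rep(1, n)
  fb <- tempheno:::tg_forward_backward(par, X, y, sw, cmap, 3L, 2L, l2 = 1e-4)
  num_grad <- function(nm, idx) {
    h <- 1e-6
    p1 <- par; p2 <- par
    p1[[nm]][idx] <- p1[[nm]][idx] + h
    p2[[nm]][idx] <- p2[[nm]][idx] - h
    (tempheno:::tg_forward_backward(p1, X, y, sw, cmap, 3L, 2L,
                                    grad = FALSE, l2 = 1e-4)$loss -
       tempheno:::tg_forward_backward(p2, X, y, sw, cmap, 3L, 2L,
                                      grad = FALSE, l2 = 1e-4)$loss) / (2 * h)
  }
  set.seed(6)
  for (nm in names(par)) {
    for (idx in sample(length(par[[nm]]), min(4, length(par[[nm]])))) {
      expect_equal(fb$grads[[nm]][idx], num_grad(nm, idx), tolerance = 1e-4)
    }
  }
})

test_that("zero training epochs leave the seeded initialization untouched", {
  d <- simulate_rule_data(n = 80, seed = 3)
  f1 <- fit_tgfnn(d$features, d$labels, epochs = 0, seed = 9,
                  val_fraction = 0)
  f2 <- fit_tgfnn(d$features, d$labels, epochs = 0, seed = 9,
                  val_fraction = 0)
  expect_identical(f1$par, f2$par)
  expect_length(f1$history, 0)
  f3 <- fit_tgfnn(d$features, d$labels, epochs = 20, seed = 9,
                  val_fraction = 0)
  expect_false(identical(f1$par$Araw, f3$par$Araw))
  expect_error(fit_tgfnn(d$features, rep(1, 80)), "single-class")
})

test_that("training on permuted labels yields chance-level discrimination", {
  aurocs <- sapply(1:5, function(s) {
    d <- simulate_rule_data(n = 220, seed = 40 + s)
    set.seed(s)
    y_perm <- sample(d$labels)
    fit <- fit_tgfnn(d$features, y_perm, class_weights = c("0" = 1, "1" = 1),
                     n_rules = 3, epochs = 120, learning_rate = 0.1,
                     seed = s, val_fraction = 0)
    te <- simulate_rule_data(n = 300, seed = 90 + s)
    binary_metrics(predict(fit, te$features)[, "1"], te$labels)$auroc
  })
  expect_lt(abs(mean(aurocs) - 0.5), 0.1)
  expect_true(all(aurocs > 0.3 & aurocs < 0.7))
})

test_that("rule extraction prunes, orders and renders hand-built rules", {
  expect_equal(formals(extract_rules)$threshold, 0.1)
  set.seed(2)
  m <- make_hand_tgfnn()
  rules <- extract_rules(m, threshold = 0.1)
  txt <- attr(rules, "text")
  expect_length(txt, 2)
  expect_match(txt[1], "x1 is high AND x2 is low")
  expect_match(txt[2], "x3 is present")
  # equal rule importances: contributions are all 1 / n_rules
  expect_equal(unique(rules$rule_contribution), 0.5)
  expect_equal(unique(rules$rule_importance), 1)
  # a dominated rule disappears below the pruning threshold
  m2 <- make_hand_tgfnn(u = matrix(c(0.1, 0.1, 2, 0.05), 2, 2))
  r2 <- extract_rules(m2, threshold = 0.1)
  expect_setequal(unique(r2$rule), 1L)
})

test_that("tidy and glance summarize a fitted network", {
  set.seed(3)
  m <- make_hand_tgfnn()
  td <- tidy(m)
  expect_setequal(names(td), c("rule", "variable", "concept", "attention",
                               "variable_weight", "rule_importance"))
  expect_equal(nrow(td), 2 * m$cmap$n_concepts)
  g <- glance(m)
  expect_equal(g$n_rules, 2)
  expect_equal(g$tnorm, 0.5)
})

test_that("the classifier contract exposes TGFNN importances", {
  d <- simulate_rule_data(n = 250, seed = 21)
  fit <- fit_classifier("tgfnn", d$features, d$labels, seed = 2,
                        params = list(epochs = 150, n_rules = 3,
                                      learning_rate = 0.1))
  sc <- predict_scores(fit, d$features)
  expect_true(all(sc >= 0 & sc <= 1))
  imp <- importances(fit)
  expect_setequal(imp$feature, setdiff(names(d$features), "patient_id"))
  expect_true(all(is.finite(imp$importance)))
})
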