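# Tropical-geometry fuzzy-rule neural network.
#
# Architecture: an encoding module maps each continuous variable to its
# membership in the concepts low / medium / high via trainable Gaussian
# membership functions (binary variables pass through as absent/present); a
# rule module learns, per rule, concept-attention weights (softmax over the
# three concepts of each variable) and non-negative variable-importance
# weights, and aggregates the attended memberships with a parameterized
# T-norm that interpolates continuously between product and minimum (the
# fuzzy AND); an inference module aggregates rule-importance-weighted rule
# strengths with a parameterized T-conorm interpolating between sum and
# maximum (the fuzzy OR, the max end being the tropical semiring operation),
# followed by softmax over classes. Training is full-batch Adam on
# class-weighted cross-entropy with manually derived gradients.

EPS_M <- 1e-6   # membership floor so logs stay finite

# ---- concept bookkeeping ---------------------------------------------------

# Build the concept map of a feature matrix: continuous variables get three
# Gaussian concepts, binary (<= 2 distinct training values) get fixed
# absent/present concepts.
build_concept_map <- function(X) {
  V <- ncol(X)
  type <- vapply(seq_len(V), function(j) {
    u <- unique(X[, j][!is.na(X[, j])])
    if (length(u) <= 2 && all(u %in% c(0, 1))) "bin" else "cont"
  }, character(1))
  labels <- list(cont = c("low", "medium", "high"),
                 bin = c("absent", "present"))
  concept_var <- integer(0); concept_label <- character(0)
  for (j in seq_len(V)) {
    lab <- labels[[type[j]]]
    concept_var <- c(concept_var, rep(j, length(lab)))
    concept_label <- c(concept_label, lab)
  }
  is_gauss <- type[concept_var] == "cont"
  g_var <- match(concept_var[is_gauss], which(type == "cont"))
  g_level <- match(concept_label[is_gauss], labels$cont)
  list(features = colnames(X), V = V, type = type,
       concept_var = concept_var, concept_label = concept_label,
       n_concepts = length(concept_var), is_gauss = is_gauss,
       g_var = g_var, g_level = g_level,
       n_cont = sum(type == "cont"))
}

# Membership matrix (n x n_concepts) from scaled inputs.
tg_memberships <- function(X, cmap, mu, rho) {
  n <- nrow(X)
  M <- matrix(0, n, cmap$n_concepts)
  sigma <- exp(rho)
  for (c_i in seq_len(cmap$n_concepts)) {
    v <- cmap$concept_var[c_i]
    if (cmap$type[v] == "bin") {
      M[, c_i] <- if (cmap$concept_label[c_i] == "present") X[, v] else
        1 - X[, v]
    }
  }
  gi <- which(cmap$is_gauss)
  for (idx in seq_along(gi)) {
    c_i <- gi[idx]
    j <- cmap$g_var[idx]; l <- cmap$g_level[idx]
    x <- X[, cmap$concept_var[c_i]]
    M[, c_i] <- exp(-(x - mu[l, j])^2 / (2 * sigma[l, j]^2))
  }
  pmin(pmax(M, EPS_M), 1)
}

# ---- public encoding/inference operations ----------------------------------

#' Gaussian membership parameters
#'
#' Three concept functions (low, medium, high) per continuous variable, each
#' a Gaussian with a center and a width.
#'
#' @param centers,widths 3 x V numeric matrices (rows: low, medium, high).
#' @return An object of class `membership_params`.
#' @export
membership_params <- function(centers, widths) {
  centers <- as.matrix(centers); widths <- as.matrix(widths)
  stopifnot(nrow(centers) == 3, all(dim(centers) == dim(widths)))
  if (any(widths <= 0)) abort("widths must be > 0")
  structure(list(centers = centers, widths = widths),
            class = "membership_params")
}

#' Fuzzify continuous variables into concept memberships
#'
#' Maps each continuous variable to its membership in the concepts low,
#' medium and high (each in \[0, 1\]; 1 at the concept's center). Binary
#' variables pass through as the pair (absent, present) = (1 - x, x).
#'
#' @param x Numeric matrix or tibble of variables (continuous columns
#'   fuzzified; 0/1 columns passed through).
#' @param params A [membership_params()] whose columns cover the continuous
#'   variables, in order.
#' @return Membership matrix with one column per concept, named
#'   `<variable>.<concept>`.
#' @export
fuzzify <- function(x, params) {
  X <- if (is.data.frame(x)) fm_matrix(x) else as.matrix(x)
  if (any(!is.finite(X))) abort("non-finite input")
  cmap <- build_concept_map(X)
  if (ncol(params$centers) != cmap$n_cont) {
    abort("`params` must provide one column per continuous variable")
  }
  M <- tg_memberships(X, cmap, params$centers, log(params$widths))
  colnames(M) <- paste(cmap$features[cmap$concept_var], cmap$concept_label,
                       sep = ".")
  M
}

#' Assemble a fuzzy rule bank
#'
#' @param alpha Rule x concept attention weights; within each (rule,
#'   variable) block the weights must be non-negative and sum to 1.
#' @param w Rule x variable importance weights, non-negative.
#' @param u Rule x class importance weights, non-negative.
#' @param tnorm T-norm interpolation in \[0, 1\]: 0 = product, 1 = minimum.
#' @param tconorm T-conorm interpolation in \[0, 1\]: 0 = sum, 1 = maximum.
#' @param concept_var Integer vector mapping each concept column to its
#'   variable.
#' @param bias Per-class additive logit bias (default 0).
#' @return An object of class `rule_bank`.
#' @export
rule_bank <- function(alpha, w, u, tnorm = 0, tconorm = 0, concept_var,
                      bias = rep(0, ncol(u))) {
  alpha <- as.matrix(alpha); w <- as.matrix(w); u <- as.matrix(u)
  stopifnot(ncol(alpha) == length(concept_var),
            nrow(alpha) == nrow(w), nrow(w) == nrow(u))
  if (any(alpha < 0) || any(w < 0) || any(u < 0)) {
    abort("attention and importance weights must be non-negative")
  }
  for (v in unique(concept_var)) {
    s <- rowSums(alpha[, concept_var == v, drop = FALSE])
    if (any(abs(s - 1) > 1e-8)) {
      abort("per-(rule, variable) concept weights must sum to 1")
    }
  }
  if (tnorm < 0 || tnorm > 1 || tconorm < 0 || tconorm > 1) {
    abort("interpolation parameters must lie in [0, 1]")
  }
  stopifnot(length(bias) == ncol(u))
  structure(list(alpha = alpha, w = w, u = u, tnorm = tnorm,
                 tconorm = tconorm, concept_var = as.integer(concept_var),
                 bias = bias, n_rules = nrow(w)),
            class = "rule_bank")
}

# Indicator matrix (n_concepts x V) summing concepts into variables.
concept_indicator <- function(concept_var) {
  V <- max(concept_var)
  Bm <- matrix(0, length(concept_var), V)
  Bm[cbind(seq_along(concept_var), concept_var)] <- 1
  Bm
}

row_mins <- function(a) do.call(pmin, as.data.frame(a))

#' Rule activation strengths
#'
#' Per rule: the attention-weighted membership of each variable is raised to
#' the variable's importance weight (weight 0 contributes neutrally, as 1)
#' and the results are combined with the parameterized T-norm
#' `(1 - t) * product + t * minimum`.
#'
#' @param memberships Membership matrix in \[0, 1\] (samples x concepts).
#' @param bank A [rule_bank()].
#' @return Matrix of rule strengths in \[0, 1\] (samples x rules).
#' @export
rule_activation <- function(memberships, bank) {
  M <- pmin(pmax(as.matrix(memberships), EPS_M), 1)
  Bm <- concept_indicator(bank$concept_var)
  n <- nrow(M)
  Fm <- matrix(0, n, bank$n_rules)
  for (r in seq_len(bank$n_rules)) {
    S <- (M * rep(bank$alpha[r, ], each = n)) %*% Bm
    S <- pmin(pmax(S, EPS_M), 1)
    loga <- log(S) * rep(bank$w[r, ], each = n)
    P <- exp(rowSums(loga))
    mn <- row_mins(exp(loga))
    Fm[, r] <- (1 - bank$tnorm) * P + bank$tnorm * mn
  }
  Fm
}

#' Class probabilities from rule strengths
#'
#' Per class, the rule-importance-weighted strengths are aggregated with the
#' parameterized T-conorm `(1 - s) * sum + s * maximum`, then softmax over
#' classes.
#'
#' @param strengths Rule strength matrix (samples x rules), non-negative.
#' @param bank A [rule_bank()].
#' @return Probability matrix (samples x classes), rows summing to 1.
#' @export
tgfnn_infer <- function(strengths, bank) {
  Fm <- as.matrix(strengths)
  if (any(Fm < 0)) abort("strengths must be non-negative")
  n <- nrow(Fm); K <- ncol(bank$u)
  logits <- matrix(0, n, K)
  for (k in seq_len(K)) {
    q <- Fm * rep(bank$u[, k], each = n)
    z <- rowSums(q)
    mx <- do.call(pmax, as.data.frame(q))
    logits[, k] <- (1 - bank$tconorm) * z + bank$tconorm * mx + bank$bias[k]
  }
  p <- exp(logits - apply(logits, 1, max))
  p / rowSums(p)
}

# ---- training --------------------------------------------------------------

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_grad <- function(x) plogis(x)

blockwise_softmax <- function(raw, concept_var) {
  out <- raw
  for (v in unique(concept_var)) {
    cols <- which(concept_var == v)
    block <- raw[, cols, drop = FALSE]
    e <- exp(block - apply(block, 1, max))
    out[, cols] <- e / rowSums(e)
  }
  out
}

# Forward + loss + analytic gradients for one full batch. Returns the loss
# and the gradient list; heavy intermediates are kept per rule.
tg_forward_backward <- function(par, X, y, sample_w, cmap, n_rules, K,
                                grad = TRUE, l2 = 1e-4) {
  n <- nrow(X)
  mu <- par$mu; rho <- par$rho; sigma <- exp(rho)
  alpha <- blockwise_softmax(par$Araw, cmap$concept_var)
  w <- softplus(par$Wraw)
  u <- softplus(par$Uraw)
  tn <- plogis(par$traw); sn <- plogis(par$sraw)
  Bm <- concept_indicator(cmap$concept_var)

  M <- tg_memberships(X, cmap, mu, rho)
  S_list <- a_list <- logS_list <- vector("list", n_rules)
  Fm <- matrix(0, n, n_rules)
  P_mat <- mn_mat <- matrix(0, n, n_rules)
  argmin_mat <- matrix(0L, n, n_rules)
  for (r in seq_len(n_rules)) {
    Sr <- (M * rep(alpha[r, ], each = n)) %*% Bm
    Sr <- pmin(pmax(Sr, EPS_M), 1)
    logSr <- log(Sr)
    loga <- logSr * rep(w[r, ], each = n)
    a <- exp(loga)
    P <- exp(rowSums(loga))
    am <- max.col(-a, ties.method = "first")
    mn <- a[cbind(seq_len(n), am)]
    S_list[[r]] <- Sr; logS_list[[r]] <- logSr; a_list[[r]] <- a
    P_mat[, r] <- P; mn_mat[, r] <- mn; argmin_mat[, r] <- am
    Fm[, r] <- (1 - tn) * P + tn * mn
  }
  q_arr <- array(0, c(n, n_rules, K))
  logits <- matrix(0, n, K)
  argmax_mat <- matrix(0L, n, K)
  for (k in seq_len(K)) {
    q <- Fm * rep(u[, k], each = n)
    q_arr[, , k] <- q
    amx <- max.col(q, ties.method = "first")
    argmax_mat[, k] <- amx
    logits[, k] <- (1 - sn) * rowSums(q) + sn * q[cbind(seq_len(n), amx)]
  }
  logits <- logits + rep(par$b, each = n)
  pm <- exp(logits - apply(logits, 1, max))
  pm <- pm / rowSums(pm)
  Wsum <- sum(sample_w)
  loss <- -sum(sample_w * log(pmax(pm[cbind(seq_len(n), y + 1L)], 1e-12))) /
    Wsum +
    l2 * (sum(par$Araw^2) + sum(par$Wraw^2) + sum(par$Uraw^2)) / 2
  if (!grad) return(list(loss = loss, probs = pm))

  onehot <- matrix(0, n, K); onehot[cbind(seq_len(n), y + 1L)] <- 1
  dlogit <- sample_w * (pm - onehot) / Wsum

  dF <- matrix(0, n, n_rules)
  du <- matrix(0, n_rules, K)
  dsn <- 0
  for (k in seq_len(K)) {
    G <- matrix(1 - sn, n, n_rules)
    G[cbind(seq_len(n), argmax_mat[, k])] <-
      G[cbind(seq_len(n), argmax_mat[, k])] + sn
    dq <- dlogit[, k] * G
    du[, k] <- colSums(dq * Fm)
    dF <- dF + dq * rep(u[, k], each = n)
    mxv <- q_arr[, , k][cbind(seq_len(n), argmax_mat[, k])]
    dsn <- dsn + sum(dlogit[, k] * (mxv - rowSums(q_arr[, , k])))
  }

  dM <- matrix(0, n, cmap$n_concepts)
  dalpha <- matrix(0, n_rules, cmap$n_concepts)
  dw <- matrix(0, n_rules, cmap$V)
  dtn <- 0
  for (r in seq_len(n_rules)) {
    dP <- (1 - tn) * dF[, r]
    dmn <- tn * dF[, r]
    dtn <- dtn + sum(dF[, r] * (mn_mat[, r] - P_mat[, r]))
    dloga <- matrix(dP * P_mat[, r], n, cmap$V)
    am <- argmin_mat[, r]
    idx <- cbind(seq_len(n), am)
    dloga[idx] <- dloga[idx] + dmn * mn_mat[, r]
    dw[r, ] <- colSums(dloga * logS_list[[r]])
    dlogS <- dloga * rep(w[r, ], each = n)
    interior <- S_list[[r]] > EPS_M & S_list[[r]] < 1
    dS <- (dlogS / S_list[[r]]) * interior
    dSfull <- dS %*% t(Bm)                      # back to concept columns
    dalpha[r, ] <- colSums(dSfull * M)
    dM <- dM + dSfull * rep(alpha[r, ], each = n)
  }

  # membership gradients -> Gaussian parameters
  dmu <- matrix(0, 3, cmap$n_cont); drho <- matrix(0, 3, cmap$n_cont)
  gi <- which(cmap$is_gauss)
  Mi <- M > EPS_M & M < 1
  for (idx in seq_along(gi)) {
    c_i <- gi[idx]
    j <- cmap$g_var[idx]; l <- cmap$g_level[idx]
    x <- X[, cmap$concept_var[c_i]]
    mcol <- M[, c_i]
    g <- dM[, c_i] * Mi[, c_i] * mcol
    dmu[l, j] <- sum(g * (x - mu[l, j]) / sigma[l, j]^2)
    drho[l, j] <- sum(g * (x - mu[l, j])^2 / sigma[l, j]^2)  # d/drho, sigma=e^rho
  }

  # attention softmax backward per (rule, variable) block
  dAraw <- matrix(0, n_rules, cmap$n_concepts)
  for (v in seq_len(cmap$V)) {
    cols <- which(cmap$concept_var == v)
    al <- alpha[, cols, drop = FALSE]
    g <- dalpha[, cols, drop = FALSE]
    dAraw[, cols] <- al * (g - rowSums(al * g))
  }

  grads <- list(mu = dmu, rho = drho, b = colSums(dlogit),
                Araw = dAraw + l2 * par$Araw,
                Wraw = dw * softplus_grad(par$Wraw) + l2 * par$Wraw,
                Uraw = du * softplus_grad(par$Uraw) + l2 * par$Uraw,
                traw = dtn * tn * (1 - tn),
                sraw = dsn * sn * (1 - sn))
  list(loss = loss, probs = pm, grads = grads)
}

adam_step <- function(state, par, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, par = par)
}

#' Fit the tropical-geometry fuzzy-rule network
#'
#' Trains membership functions, concept attention, variable and rule
#' importances, and the T-norm/T-conorm interpolation parameters by Adam on
#' class-weighted cross-entropy. Continuous features are min-max scaled from
#' training statistics; Gaussian concept centers are initialized at the
#' training 25th/50th/75th percentiles with widths at half the inter-quartile
#' gap. A held-out fraction of the training data is used for early stopping
#' on F1 (best checkpoint kept).
#'
#' @param features Wide feature tibble (no missing values).
#' @param labels 0/1 outcomes.
#' @param class_weights Named per-class weights (default
#'   [class_weights()] of `labels`).
#' @param n_rules Number of rules (default 8).
#' @param learning_rate Adam step size (default 0.05).
#' @param epochs Full-batch epochs (default 300).
#' @param seed Integer seed.
#' @param val_fraction Early-stopping holdout fraction (default 0.15; 0
#'   disables early stopping).
#' @param tnorm_init,tconorm_init Initial interpolation parameters in (0, 1).
#' @param l2 Weight decay on the rule-module parameters.
#' @param check_every Epoch interval between early-stopping checks.
#' @return An object of class `tgfnn`; see [predict.tgfnn()],
#'   [extract_rules()], [tidy.tgfnn()].
#' @export
fit_tgfnn <- function(features, labels, class_weights = NULL, n_rules = 8L,
                      learning_rate = 0.05, epochs = 300L, seed = 1L,
                      val_fraction = 0.15, tnorm_init = 0.1,
                      tconorm_init = 0.1, l2 = 1e-4, check_every = 10L) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2) abort("single-class training data")
  X0 <- fm_matrix(features)
  if (anyNA(X0)) abort("missing values must be imputed before fitting")
  cw <- class_weights %||% .class_weights(y)
  rng <- apply(X0, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-12)
  scale_x <- function(M) sweep(sweep(M, 2, rng[1, ]), 2, span, "/")
  X <- scale_x(X0)
  cmap <- build_concept_map(X)

  qs <- apply(X[, cmap$type == "cont", drop = FALSE], 2, quantile,
              probs = c(0.25, 0.5, 0.75))
  if (cmap$n_cont == 0) qs <- matrix(0, 3, 0)
  widths <- pmax((qs[3, ] - qs[1, ]) / 2, 0.05)
  par <- with_seed(seed, list(
    mu = matrix(qs, 3, cmap$n_cont),
    rho = matrix(log(rep(widths, each = 3)), 3, cmap$n_cont),
    Araw = matrix(rnorm(n_rules * cmap$n_concepts, 0, 0.5), n_rules),
    Wraw = matrix(rnorm(n_rules * cmap$V, -0.5, 0.7), n_rules),
    Uraw = cbind(rnorm(n_rules, -1, 0.3), rnorm(n_rules, 0.5, 0.3)),
    b = c(2, -2),
    traw = qlogis(tnorm_init), sraw = qlogis(tconorm_init)
  ))

  n <- nrow(X)
  if (val_fraction > 0) {
    val_idx <- with_seed(seed + 1L, {
      sort(unlist(lapply(unique(y), function(cl) {
        cand <- which(y == cl)
        sample(cand, max(1L, round(val_fraction * length(cand))))
      })))
    })
  } else val_idx <- integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  sw <- unname(cw[as.character(y)])

  state <- list(t = 0L, m = purrr::map(par, function(p) p * 0),
                v = purrr::map(par, function(p) p * 0))
  best <- list(par = par, f1 = -Inf, epoch = 0L)
  history <- numeric(0)
  for (ep in seq_len(max(epochs, 0L))) {
    fb <- tg_forward_backward(par, X[tr_idx, , drop = FALSE], y[tr_idx],
                              sw[tr_idx], cmap, n_rules, K = 2L, l2 = l2)
    history <- c(history, fb$loss)
    st <- adam_step(state, par, fb$grads, lr = learning_rate)
    state <- st$state; par <- st$par
    if (length(val_idx) > 0 &&
        (ep %% check_every == 0 || ep == epochs)) {
      fv <- tg_forward_backward(par, X[val_idx, , drop = FALSE], y[val_idx],
                                sw[val_idx], cmap, n_rules, K = 2L,
                                grad = FALSE, l2 = 0)
      f1 <- binary_metrics(fv$probs[, 2], y[val_idx])$f1
      if (f1 > best$f1) best <- list(par = par, f1 = f1, epoch = ep)
    }
  }
  final_par <- if (length(val_idx) > 0 && best$epoch > 0) best$par else par
  obj <- structure(list(par = final_par, cmap = cmap, n_rules = n_rules,
                        scaling = list(min = rng[1, ], span = span),
                        class_weights = cw, history = history,
                        best_val_f1 = best$f1, best_epoch = best$epoch,
                        seed = seed, epochs = epochs),
                   class = "tgfnn")
  obj$effect <- tgfnn_rule_effects(obj, X)
  obj
}

# Per-rule, per-variable effect weights: the variable's importance weight
# times its mean attended negative-log-membership over the training data,
# i.e. its average contribution to the rule's log-activation. A concept
# squashed to be always true contributes nothing, however large its raw
# weight.
tgfnn_rule_effects <- function(object, X_scaled) {
  bank <- tgfnn_bank(object)
  M <- tg_memberships(X_scaled, object$cmap, object$par$mu, object$par$rho)
  Bm <- concept_indicator(bank$concept_var)
  n <- nrow(M)
  eff <- matrix(0, bank$n_rules, object$cmap$V,
                dimnames = list(NULL, object$cmap$features))
  for (r in seq_len(bank$n_rules)) {
    S <- (M * rep(bank$alpha[r, ], each = n)) %*% Bm
    S <- pmin(pmax(S, EPS_M), 1)
    eff[r, ] <- bank$w[r, ] * colMeans(-log(S))
  }
  eff
}

# Transformed parameter view of a fitted network.
tgfnn_bank <- function(object) {
  p <- object$par
  rule_bank(alpha = blockwise_softmax(p$Araw, object$cmap$concept_var),
            w = softplus(p$Wraw), u = softplus(p$Uraw),
            tnorm = plogis(p$traw), tconorm = plogis(p$sraw),
            concept_var = object$cmap$concept_var, bias = p$b)
}

#' @export
print.tgfnn <- function(x, ...) {
  cat("<tgfnn>", x$n_rules, "rules,", x$cmap$V, "variables,",
      x$cmap$n_concepts, "concepts; trained", x$epochs, "epochs\n")
  invisible(x)
}

#' Predict class probabilities from a fitted TGFNN
#'
#' @param object A `tgfnn`.
#' @param newdata Wide feature tibble with the training columns.
#' @param ... Unused.
#' @return Probability matrix with columns `"0"` and `"1"`.
#' @export
predict.tgfnn <- function(object, newdata, ...) {
  X0 <- fm_matrix(newdata)[, object$cmap$features, drop = FALSE]
  X <- sweep(sweep(X0, 2, object$scaling$min), 2, object$scaling$span, "/")
  M <- tg_memberships(X, object$cmap, object$par$mu, object$par$rho)
  bank <- tgfnn_bank(object)
  p <- tgfnn_infer(rule_activation(M, bank), bank)
  colnames(p) <- c("0", "1")
  p
}

# Global variable importance: rule-importance-weighted per-rule effect
# weights for the positive class.
tgfnn_variable_importance <- function(object) {
  bank <- tgfnn_bank(object)
  upos <- bank$u[, 2]
  w_eff <- object$effect %||% bank$w
  imp <- colSums((upos / max(sum(upos), 1e-12)) * w_eff)
  setNames(imp, object$cmap$features)
}

#' Extract human-readable rules from a fitted TGFNN
#'
#' Rules are scored by their positive-class importance relative to the
#' largest; rules and, within a rule, variables whose relative importance
#' falls below `threshold` are pruned. Each retained variable is rendered as
#' its highest-attention concept ("x is low/medium/high", or
#' "absent/present" for binary variables).
#'
#' @param object A fitted `tgfnn`.
#' @param threshold Relative-importance pruning threshold (default 0.1).
#' @return A tibble (rule, rule_importance, rule_contribution, variable,
#'   variable_weight, concept, concept_weight), sorted by rule importance
#'   (relative to the largest rule; `rule_contribution` is the share of the
#'   total), with the rendered rule sentences in `attr(, "text")`.
#' @export
extract_rules <- function(object, threshold = 0.1) {
  bank <- tgfnn_bank(object)
  cmap <- object$cmap
  upos <- bank$u[, 2]
  rel <- upos / max(upos)
  contrib <- upos / sum(upos)        # share of total rule importance
  keep_rules <- which(rel >= threshold)
  keep_rules <- keep_rules[order(rel[keep_rules], decreasing = TRUE)]
  rows <- list(); texts <- character(0)
  w_eff <- object$effect %||% bank$w
  for (r in keep_rules) {
    wv <- w_eff[r, ]
    wrel <- wv / max(wv)
    vars <- which(wrel >= threshold)
    vars <- vars[order(wrel[vars], decreasing = TRUE)]
    if (length(vars) == 0) next
    terms <- character(0)
    for (v in vars) {
      cols <- which(cmap$concept_var == v)
      best <- cols[which.max(bank$alpha[r, cols])]
      cl <- cmap$concept_label[best]
      verb <- if (cmap$type[v] == "bin") "is" else "is"
      terms <- c(terms, paste(cmap$features[v], verb, cl))
      rows[[length(rows) + 1L]] <- tibble(
        rule = r, rule_importance = rel[r], rule_contribution = contrib[r],
        variable = cmap$features[v], variable_weight = wrel[v],
        concept = cl, concept_weight = bank$alpha[r, best])
    }
    texts <- c(texts, sprintf(
      "R%d (importance %.2f): IF %s THEN outcome is likely",
      r, rel[r], paste(terms, collapse = " AND ")))
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(rule = integer(), rule_importance = numeric(),
           rule_contribution = numeric(),
           variable = character(), variable_weight = numeric(),
           concept = character(), concept_weight = numeric())
  attr(out, "text") <- texts
  class(out) <- c("tgfnn_rules", class(out))
  out
}

#' @export
print.tgfnn_rules <- function(x, ...) {
  for (line in attr(x, "text")) cat(line, "\n")
  NextMethod()
}

#' Tidy a fitted TGFNN into a rule-by-concept weight table
#'
#' Heatmap-ready: one row per (rule, variable, concept) with the attention
#' and importance weights.
#'
#' @param x A `tgfnn`.
#' @param ... Unused.
#' @return Tibble (rule, variable, concept, attention, variable_weight,
#'   rule_importance).
#' @method tidy tgfnn
#' @export
tidy.tgfnn <- function(x, ...) {
  bank <- tgfnn_bank(x)
  cmap <- x$cmap
  upos <- bank$u[, 2]
  purrr::map_dfr(seq_len(bank$n_rules), function(r) {
    tibble(rule = r,
           variable = cmap$features[cmap$concept_var],
           concept = cmap$concept_label,
           attention = bank$alpha[r, ],
           variable_weight = bank$w[r, cmap$concept_var],
           rule_importance = upos[r] / max(upos))
  })
}

#' One-row training summary of a fitted TGFNN
#'
#' @param x A `tgfnn`.
#' @param ... Unused.
#' @return Tibble (n_rules, n_variables, final_loss, best_val_f1,
#'   best_epoch, tnorm, tconorm).
#' @method glance tgfnn
#' @export
glance.tgfnn <- function(x, ...) {
  tibble(n_rules = x$n_rules, n_variables = x$cmap$V,
         final_loss = if (length(x$history)) tail(x$history, 1) else NA_real_,
         best_val_f1 = x$best_val_f1, best_epoch = x$best_epoch,
         tnorm = plogis(x$par$traw), tconorm = plogis(x$par$sraw))
}

#' Rule-by-concept heatmap of a fitted TGFNN
#'
#' @param object A `tgfnn`.
#' @param threshold Concepts with attention * variable weight below this
#'   relative level are blanked.
#' @param ... Unused.
#' @return A ggplot heatmap (rules on x, variable concepts on y).
#' @method autoplot tgfnn
#' @export
autoplot.tgfnn <- function(object, threshold = 0.1, ...) {
  df <- tidy(object) %>%
    mutate(cell = .data$attention * .data$variable_weight,
           label = paste(.data$variable, .data$concept, sep = "."))
  df <- df %>% mutate(cell = ifelse(.data$cell < threshold * max(.data$cell),
                                    NA, .data$cell))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$rule), y = .data$label,
                                   fill = .data$cell)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 na.value = "grey95") +
    ggplot2::labs(x = "rule", y = NULL, fill = "weight")
}
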