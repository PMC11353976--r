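# Independent oracles and fixture builders shared across tests. Each oracle
# recomputes a quantity from first principles (loops, enumeration, dense grid
# search) and stays independent of the package code paths it checks.

# ---- tensors ---------------------------------------------------------------

# Dense rank-R tensor from factor triples (triple loop, intentionally naive).
outer3_oracle <- function(lambda, A, B, C) {
  d <- c(nrow(A), nrow(B), nrow(C))
  out <- array(0, d)
  for (r in seq_along(lambda)) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      out[i, j, k] <- out[i, j, k] + lambda[r] * A[i, r] * B[j, r] * C[k, r]
    }
  }
  out
}

# Planted non-negative CP tensor with optional Gaussian noise at a target
# amplitude signal-to-noise ratio (||signal|| / ||noise||).
make_planted_tensor <- function(dims, rank, seed, snr = Inf) {
  set.seed(seed)
  A <- matrix(runif(dims[1] * rank, 0.1, 1), dims[1])
  B <- matrix(runif(dims[2] * rank, 0.1, 1), dims[2])
  C <- matrix(runif(dims[3] * rank, 0.1, 1), dims[3])
  S <- array(0, dims)
  for (r in seq_len(rank)) S <- S + outer(outer(A[, r], B[, r]), C[, r])
  X <- S
  if (is.finite(snr)) {
    noise <- array(rnorm(prod(dims)), dims)
    noise <- noise * sqrt(sum(S^2)) / (snr * sqrt(sum(noise^2)))
    X <- pmax(S + noise, 0)
  }
  list(tensor = X, signal = S, A = A, B = B, C = C)
}

cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

# Mean matched-factor congruence: greedily pair estimated components with
# true ones by the product of per-mode cosines, then average the per-mode
# cosines of the matched pairs.
cp_congruence <- function(model, A, B, C) {
  R <- ncol(A)
  score <- matrix(0, R, R)
  for (r in seq_len(R)) for (s in seq_len(R)) {
    score[r, s] <- cosine(A[, r], model$A[, s]) *
      cosine(B[, r], model$B[, s]) * cosine(C[, r], model$C[, s])
  }
  used <- logical(R); total <- 0
  for (r in order(apply(score, 1, max), decreasing = TRUE)) {
    s <- order(score[r, ], decreasing = TRUE)
    s <- s[!used[s]][1]
    used[s] <- TRUE
    total <- total + (cosine(A[, r], model$A[, s]) +
                        cosine(B[, r], model$B[, s]) +
                        cosine(C[, r], model$C[, s])) / 3
  }
  total / R
}

# Reference CP solver: plain unconstrained ALS via pseudo-inverse updates.
# Deliberately a different algorithm from the package's non-negative HALS.
als_reference <- function(tensor, rank, seed, iters = 200L) {
  d <- dim(tensor)
  set.seed(seed)
  A <- matrix(rnorm(d[1] * rank), d[1])
  B <- matrix(rnorm(d[2] * rank), d[2])
  C <- matrix(rnorm(d[3] * rank), d[3])
  unf <- function(a, mode) {
    dd <- dim(a)
    switch(mode,
           matrix(a, dd[1], dd[2] * dd[3]),
           matrix(aperm(a, c(2, 1, 3)), dd[2], dd[1] * dd[3]),
           matrix(aperm(a, c(3, 1, 2)), dd[3], dd[1] * dd[2]))
  }
  kr <- function(X, Y) {
    X[rep(seq_len(nrow(X)), each = nrow(Y)), , drop = FALSE] *
      Y[rep(seq_len(nrow(Y)), times = nrow(X)), , drop = FALSE]
  }
  X1 <- unf(tensor, 1); X2 <- unf(tensor, 2); X3 <- unf(tensor, 3)
  for (it in seq_len(iters)) {
    A <- X1 %*% kr(C, B) %*% solve(crossprod(C) * crossprod(B) +
                                     diag(1e-10, rank))
    B <- X2 %*% kr(C, A) %*% solve(crossprod(C) * crossprod(A) +
                                     diag(1e-10, rank))
    C <- X3 %*% kr(B, A) %*% solve(crossprod(B) * crossprod(A) +
                                     diag(1e-10, rank))
  }
  rec <- A %*% t(kr(C, B))
  sqrt(sum((X1 - rec)^2)) / sqrt(sum(tensor^2))
}

# ---- metric oracles --------------------------------------------------------

# AUROC by all-pairs concordance with half-credit ties.
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# AUPRC as the step integral of the PR curve, looping over distinct
# thresholds explicitly.
auprc_oracle <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_rec <- 0; total <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / n_pos
    total <- total + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  total
}

# Kendall tau-b by explicit pair counting.
kendall_oracle <- function(x, y) {
  n <- length(x); conc <- 0; disc <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
    if (a == 0 && b == 0) { tx <- tx; next }
    if (a == 0) { tx <- tx + 1; next }
    if (b == 0) { ty <- ty + 1; next }
    if (a == b) conc <- conc + 1 else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  t1 <- sum(sapply(split(x, x), function(g) length(g) * (length(g) - 1) / 2))
  t2 <- sum(sapply(split(y, y), function(g) length(g) * (length(g) - 1) / 2))
  (conc - disc) / sqrt((n0 - t1) * (n0 - t2))
}

# Tie-corrected Friedman chi-square from explicit within-block ranks.
friedman_oracle <- function(M) {
  n <- nrow(M); k <- ncol(M)
  R <- t(apply(M, 1, rank))
  Rj <- colSums(R)
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  den <- sum(R^2) - n * k * (k + 1)^2 / 4
  num / den
}

# Dense grid-search oracle for Platt scaling: minimize log-loss of
# p = 1 / (1 + exp(A s + B)) over a fine (A, B) grid.
platt_grid_oracle <- function(scores, labels, a_range, b_range, steps = 200) {
  best <- list(loss = Inf)
  for (A in seq(a_range[1], a_range[2], length.out = steps)) {
    for (B in seq(b_range[1], b_range[2], length.out = steps)) {
      p <- 1 / (1 + exp(A * scores + B))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      loss <- -mean(labels * log(p) + (1 - labels) * log(1 - p))
      if (loss < best$loss) best <- list(loss = loss, A = A, B = B)
    }
  }
  best
}

log_loss <- function(p, labels) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# ---- small data builders ---------------------------------------------------

event_row <- function(patient_id, days, domain, variable, value = 1) {
  tibble::tibble(patient_id = patient_id, days_before_anchor = as.integer(days),
                 domain = domain, variable = variable, value = value)
}

tiny_cohort <- function(ids, labels = NULL, split = "train") {
  n <- length(ids)
  tibble::tibble(patient_id = ids,
                 label = labels %||% rep("control", n),
                 age = 60, sex = "M", frailty = 0,
                 matched_set_id = seq_len(n), split = split)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
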