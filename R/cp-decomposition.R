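# Non-negative CP (PARAFAC) decomposition by hierarchical alternating least
# squares (HALS), held-out patient projection, rank scanning, and phenotype
# reporting. Each rank-one component (a_r, b_r, c_r) is read as a clinical
# phenotype: which patients express it, when, and through which features.

# Khatri-Rao (column-wise Kronecker) product; row index of the result runs
# the rows of Y fastest, matching the unfoldings below.
khatri_rao <- function(X, Y) {
  K <- nrow(X); J <- nrow(Y)
  X[rep(seq_len(K), each = J), , drop = FALSE] *
    Y[rep(seq_len(J), times = K), , drop = FALSE]
}

unfold <- function(a, mode) {
  d <- dim(a)
  switch(mode,
         matrix(a, d[1], d[2] * d[3]),
         matrix(aperm(a, c(2, 1, 3)), d[2], d[1] * d[3]),
         matrix(aperm(a, c(3, 1, 2)), d[3], d[1] * d[2]))
}

# One HALS pass over the columns of factor `Fm` given the Gram matrix W of
# the other factors and the MTTKRP matrix M; entries floored at `eps`.
hals_update <- function(Fm, W, M, eps = 1e-12) {
  for (r in seq_len(ncol(Fm))) {
    if (W[r, r] <= 0) next
    num <- M[, r] - Fm %*% W[, r] + Fm[, r] * W[r, r]
    Fm[, r] <- pmax(eps, num / W[r, r])
  }
  Fm
}

#' Non-negative CP decomposition via HALS
#'
#' Fits a rank-`rank` non-negative CP model to a 3-mode tensor by column-wise
#' hierarchical alternating least squares, minimizing the Frobenius
#' reconstruction error. Factors are initialized non-negative uniform at
#' random (seeded); updates are floored at a small positive constant so no
#' column dies silently, and a column whose norm still collapses is re-seeded
#' at random (with a message). The objective is non-increasing across sweeps
#' and iteration stops when the relative improvement falls below `tol`. On
#' return the scale of each component is absorbed into `lambda` and all three
#' factor matrices have unit-norm columns.
#'
#' @param tensor An [ehr_tensor()] or a plain non-negative 3-mode array.
#' @param rank Number of components (phenotypes).
#' @param seed Integer seed for the initialization.
#' @param max_iter Maximum number of sweeps.
#' @param tol Relative-improvement stopping tolerance.
#' @return An object of class `cp_model`: `lambda`, factor matrices `A`
#'   (patient), `B` (time), `C` (feature), axis labels, the per-sweep relative
#'   error trace, and fit metadata.
#' @export
nncp_hals <- function(tensor, rank, seed = 1L, max_iter = 200L, tol = 1e-8) {
  labels <- NULL
  if (inherits(tensor, "ehr_tensor")) {
    labels <- tensor[c("patients", "bins", "features", "domain")]
    tensor <- tensor$values
  }
  stopifnot(length(dim(tensor)) == 3, rank >= 1)
  if (any(tensor < 0)) abort("tensor must be non-negative")
  d <- dim(tensor)
  if (rank > max(d)) warn("rank exceeds every mode size; model is over-parameterized")
  normT <- sqrt(sum(tensor^2))
  if (normT == 0) {
    zf <- function(n) matrix(0, n, rank)
    return(new_cp_model(rep(0, rank), zf(d[1]), zf(d[2]), zf(d[3]), labels,
                        iterations = 0L, rel_error = 0, seed = seed,
                        obj_trace = numeric(0)))
  }
  X1 <- unfold(tensor, 1); X2 <- unfold(tensor, 2); X3 <- unfold(tensor, 3)
  fac <- with_seed(seed, lapply(d, function(n) {
    matrix(runif(n * rank, 0.1, 1), n, rank)
  }))
  A <- fac[[1]]; B <- fac[[2]]; C <- fac[[3]]
  trace <- numeric(0)
  prev <- Inf
  it <- 0L
  reseed_count <- 0L
  while (it < max_iter) {
    it <- it + 1L
    A <- hals_update(A, crossprod(C) * crossprod(B), X1 %*% khatri_rao(C, B))
    B <- hals_update(B, crossprod(C) * crossprod(A), X2 %*% khatri_rao(C, A))
    W <- crossprod(B) * crossprod(A)
    M <- X3 %*% khatri_rao(B, A)
    C <- hals_update(C, W, M)
    err2 <- normT^2 - 2 * sum(C * M) + sum(crossprod(C) * W)
    rel <- sqrt(max(err2, 0)) / normT
    trace <- c(trace, rel)
    for (r in seq_len(rank)) {
      norms <- c(sqrt(sum(A[, r]^2)), sqrt(sum(B[, r]^2)), sqrt(sum(C[, r]^2)))
      if (any(norms < 1e-10)) {
        reseed_count <- reseed_count + 1L
        A[, r] <- runif(d[1], 0.1, 1); B[, r] <- runif(d[2], 0.1, 1)
        C[, r] <- runif(d[3], 0.1, 1)
        inform(sprintf("re-seeded dead component %d", r))
      }
    }
    if (is.finite(prev) && (prev - rel) < tol * max(prev, 1e-12)) break
    prev <- rel
  }
  # absorb scale into lambda, unit-norm columns
  nA <- sqrt(colSums(A^2)); nB <- sqrt(colSums(B^2)); nC <- sqrt(colSums(C^2))
  lambda <- nA * nB * nC
  sc <- function(Fm, nrm) sweep(Fm, 2, pmax(nrm, 1e-300), "/")
  model <- new_cp_model(lambda, sc(A, nA), sc(B, nB), sc(C, nC), labels,
                        iterations = it, rel_error = tail(trace, 1),
                        seed = seed, obj_trace = trace)
  model$reseeds <- reseed_count
  model
}

new_cp_model <- function(lambda, A, B, C, labels, iterations, rel_error,
                         seed, obj_trace) {
  ord <- order(lambda, decreasing = TRUE)
  structure(list(rank = length(lambda), lambda = lambda[ord],
                 A = A[, ord, drop = FALSE], B = B[, ord, drop = FALSE],
                 C = C[, ord, drop = FALSE],
                 patients = labels$patients, bins = labels$bins,
                 features = labels$features, domain = labels$domain,
                 iterations = iterations, rel_error = rel_error, seed = seed,
                 obj_trace = obj_trace),
            class = "cp_model")
}

#' @export
print.cp_model <- function(x, ...) {
  cat("<cp_model> rank", x$rank, "|", nrow(x$A), "patients x", nrow(x$B),
      "bins x", nrow(x$C), "features | rel. error",
      formatC(x$rel_error, digits = 4, format = "g"), "\n")
  invisible(x)
}

#' Reconstruct the tensor approximated by a CP model
#'
#' @param model A `cp_model`.
#' @return The 3-mode array `sum_r lambda_r a_r o b_r o c_r`.
#' @export
reconstruct <- function(model) {
  d <- c(nrow(model$A), nrow(model$B), nrow(model$C))
  rec <- sweep(model$A, 2, model$lambda, "*") %*%
    t(khatri_rao(model$C, model$B))
  array(rec, d)
}

#' Patient phenotype memberships of a CP model
#'
#' The patient factor scaled by the component weights, so a membership of m on
#' component r means the patient's slice contains m times the unit-norm
#' rank-one time-by-feature pattern of r.
#'
#' @param model A `cp_model`.
#' @return Numeric matrix, patients by components, row names = patient ids.
#' @export
cp_memberships <- function(model) {
  M <- sweep(model$A, 2, model$lambda, "*")
  rownames(M) <- model$patients
  colnames(M) <- paste0("phenotype_", seq_len(model$rank))
  M
}

#' Project new patients onto fixed phenotypes
#'
#' Holds the time and feature factors (and component weights) of a fitted
#' model fixed and solves, per new patient, a non-negative least squares
#' problem for the membership row against the Khatri-Rao basis of the fixed
#' factors. Phenotypes are unchanged; only memberships are estimated.
#'
#' @param model A `cp_model`.
#' @param new_tensor An `ehr_tensor` (or array) sharing the model's time and
#'   feature axes.
#' @param max_iter Maximum coordinate-descent sweeps of the non-negative
#'   least squares solve.
#' @param tol Stopping tolerance on the largest membership change per sweep.
#' @return Membership matrix (new patients by components).
#' @export
project_patients <- function(model, new_tensor, max_iter = 500L, tol = 1e-12) {
  pats <- NULL
  if (inherits(new_tensor, "ehr_tensor")) {
    if (!identical(new_tensor$features, model$features) ||
        !identical(new_tensor$bins, model$bins)) {
      abort("time/feature axes of `new_tensor` do not match the model")
    }
    pats <- new_tensor$patients
    new_tensor <- new_tensor$values
  }
  d <- dim(new_tensor)
  if (d[2] != nrow(model$B) || d[3] != nrow(model$C)) {
    abort("time/feature dimensions do not match the model")
  }
  Z <- khatri_rao(model$C, model$B)          # JK x R, unit-ish columns
  X <- unfold(new_tensor, 1)                 # n x JK
  G <- crossprod(Z)
  MZ <- X %*% Z
  Mem <- matrix(0, d[1], model$rank)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (r in seq_len(model$rank)) {
      if (G[r, r] <= 0) next
      new_col <- pmax(0, (MZ[, r] - Mem %*% G[, r] + Mem[, r] * G[r, r]) /
                        G[r, r])
      delta <- max(delta, max(abs(new_col - Mem[, r])))
      Mem[, r] <- new_col
    }
    if (delta < tol) break
  }
  rownames(Mem) <- pats
  colnames(Mem) <- paste0("phenotype_", seq_len(model$rank))
  Mem
}

#' Phenotype membership feature matrix
#'
#' Concatenates the memberships of one or more CP models (e.g. the lab/vital
#' and dx/rx decompositions) into a wide feature tibble for classification.
#'
#' @param models Named list of `cp_model`s sharing the patient axis, or
#'   matrices as returned by [cp_memberships()]/[project_patients()].
#' @param patient_ids Patient order for the output rows.
#' @return Wide tibble with provenance `"phenotype"`.
#' @export
phenotype_features <- function(models, patient_ids) {
  parts <- purrr::imap(models, function(m, nm) {
    M <- if (inherits(m, "cp_model")) cp_memberships(m) else m
    colnames(M) <- paste0(nm, "_", colnames(M))
    M[patient_ids, , drop = FALSE]
  })
  out <- tibble(patient_id = patient_ids)
  out <- dplyr::bind_cols(out, purrr::map(parts, as_tibble))
  set_provenance(out, "phenotype")
}

#' Scan decomposition ranks by downstream discriminability
#'
#' For each rank in `rank_grid`, fits `replicates` seeded decompositions of
#' the tensor restricted to a random (label-stratified) subset of patients,
#' projects the held-out patients onto the learned phenotypes, trains a
#' random-forest reference classifier on the memberships, and records
#' F1/AUROC/AUPRC on the held-out patients. The returned table carries a
#' maximum-curvature elbow suggestion in `attr(, "suggested_rank")`; the final
#' rank remains the analyst's choice.
#'
#' @param tensor An `ehr_tensor`.
#' @param labels 0/1 outcome per tensor patient.
#' @param rank_grid Integer ranks to scan.
#' @param replicates Decomposition replicates per rank (default 3).
#' @param val_fraction Held-out patient fraction (default 0.3).
#' @param seed Integer seed.
#' @param num_trees Trees in the reference forest.
#' @return Tibble (rank, replicate, f1, auroc, auprc).
#' @export
select_rank <- function(tensor, labels, rank_grid, replicates = 3L,
                        val_fraction = 0.3, seed = 1L, num_trees = 200L) {
  stopifnot(inherits(tensor, "ehr_tensor"),
            length(labels) == length(tensor$patients))
  rows <- list()
  for (rk in rank_grid) {
    for (rep_i in seq_len(replicates)) {
      s <- seed + 1000L * rep_i + rk
      val_idx <- with_seed(s, {
        idx <- unlist(lapply(unique(labels), function(cl) {
          cand <- which(labels == cl)
          sample(cand, max(1L, round(val_fraction * length(cand))))
        }))
        sort(idx)
      })
      if (length(unique(labels[val_idx])) < 2 ||
          length(unique(labels[-val_idx])) < 2) {
        abort("degenerate single-class validation split")
      }
      sub <- tensor
      sub$values <- tensor$values[-val_idx, , , drop = FALSE]
      sub$patients <- tensor$patients[-val_idx]
      fit <- nncp_hals(sub, rank = rk, seed = s)
      tr_mem <- cp_memberships(fit)
      va <- tensor
      va$values <- tensor$values[val_idx, , , drop = FALSE]
      va$patients <- tensor$patients[val_idx]
      va_mem <- project_patients(fit, va)
      rf <- ranger::ranger(
        x = as.data.frame(tr_mem), y = factor(labels[-val_idx]),
        probability = TRUE, num.trees = num_trees, seed = s)
      sc <- predict(rf, as.data.frame(va_mem))$predictions[, "1"]
      met <- binary_metrics(sc, labels[val_idx])
      rows[[length(rows) + 1L]] <- tibble(
        rank = rk, replicate = rep_i, f1 = met$f1, auroc = met$auroc,
        auprc = met$auprc)
    }
  }
  out <- bind_rows(rows)
  curve <- out %>% group_by(.data$rank) %>%
    summarise(auroc = mean(.data$auroc), .groups = "drop") %>%
    arrange(.data$rank)
  attr(out, "suggested_rank") <- elbow_rank(curve$rank, curve$auroc)
  out
}

# Maximum-curvature elbow: largest negative discrete second difference of the
# metric-vs-rank curve; falls back to the best rank when the grid is short.
elbow_rank <- function(ranks, metric) {
  if (length(ranks) < 3) return(ranks[which.max(metric)])
  d2 <- diff(diff(metric) / diff(ranks)) / diff(ranks)[-1]
  ranks[which.min(d2) + 1L]
}

#' Human-readable phenotype report
#'
#' Per component: the `k` highest-weighted features (descending), the temporal
#' profile, and the patient membership column rescaled to \[0, 1\] by its
#' maximum.
#'
#' @param model A `cp_model`.
#' @param k Features reported per component (default 5).
#' @return An object of class `phenotype_report` with tibbles `features`,
#'   `time_profiles`, `memberships`.
#' @export
phenotype_report <- function(model, k = 5L) {
  if (k > nrow(model$C)) abort("`k` exceeds the number of features")
  feats <- model$features %||% paste0("feature_", seq_len(nrow(model$C)))
  pats <- model$patients %||% paste0("patient_", seq_len(nrow(model$A)))
  bins <- model$bins %||% (seq_len(nrow(model$B)) - 1L)
  features <- purrr::map_dfr(seq_len(model$rank), function(r) {
    ord <- order(model$C[, r], decreasing = TRUE)[seq_len(k)]
    tibble(component = r, position = seq_len(k), feature = feats[ord],
           weight = model$C[ord, r])
  })
  time_profiles <- purrr::map_dfr(seq_len(model$rank), function(r) {
    tibble(component = r, bin = bins, weight = model$B[, r])
  })
  memberships <- purrr::map_dfr(seq_len(model$rank), function(r) {
    m <- model$A[, r] * model$lambda[r]
    mx <- max(m)
    tibble(component = r, patient_id = pats,
           membership = if (mx > 0) m / mx else m)
  })
  structure(list(features = features, time_profiles = time_profiles,
                 memberships = memberships, rank = model$rank),
            class = "phenotype_report")
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat("<phenotype_report>", x$rank, "components; top features:\n")
  print(x$features, n = min(nrow(x$features), 20))
  invisible(x)
}

#' Tidy a CP model into a long factor table
#'
#' @param x A `cp_model`.
#' @param ... Unused.
#' @return Tibble (component, mode, label, weight, lambda).
#' @method tidy cp_model
#' @export
tidy.cp_model <- function(x, ...) {
  lab <- list(patient = x$patients %||% as.character(seq_len(nrow(x$A))),
              time = as.character(x$bins %||% (seq_len(nrow(x$B)) - 1L)),
              feature = x$features %||% as.character(seq_len(nrow(x$C))))
  fm <- list(patient = x$A, time = x$B, feature = x$C)
  purrr::map_dfr(names(fm), function(md) {
    purrr::map_dfr(seq_len(x$rank), function(r) {
      tibble(component = r, mode = md, label = lab[[md]],
             weight = fm[[md]][, r], lambda = x$lambda[r])
    })
  })
}

#' One-row fit summary of a CP model
#'
#' @param x A `cp_model`.
#' @param ... Unused.
#' @return Tibble with rank, relative error, iterations, seed.
#' @method glance cp_model
#' @export
glance.cp_model <- function(x, ...) {
  tibble(rank = x$rank, rel_error = x$rel_error, iterations = x$iterations,
         reseeds = x$reseeds %||% 0L, seed = x$seed)
}

#' Plot the temporal profiles of a CP model
#'
#' @param object A `cp_model`.
#' @param ... Unused.
#' @return A ggplot: one line per component over time bins (bin 9 adjacent to
#'   the anchor).
#' @method autoplot cp_model
#' @export
autoplot.cp_model <- function(object, ...) {
  df <- tidy(object) %>% filter(.data$mode == "time") %>%
    mutate(bin = as.integer(.data$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$weight)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = "six-month bin (9 = closest to anchor)",
                  y = "temporal weight")
}

#' Plot a rank scan
#'
#' @param scan Output of [select_rank()].
#' @return A ggplot of metric vs rank with the elbow suggestion marked.
#' @export
plot_rank_scan <- function(scan) {
  df <- scan %>%
    tidyr::pivot_longer(c("f1", "auroc", "auprc"), names_to = "metric")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$value)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(y = "held-out metric")
  sug <- attr(scan, "suggested_rank")
  if (!is.null(sug)) p <- p + ggplot2::geom_vline(xintercept = sug,
                                                  linetype = "dashed")
  p
}
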