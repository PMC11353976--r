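# End-to-end synthetic study: generate a matched cohort, preprocess, build
# the three feature representations (latest + demographics, summary
# statistics, temporal phenotypes from the two tensor decompositions), and
# evaluate a classifier per feature set on the held-out test split.

#' Run the full phenotyping pipeline on a synthetic cohort
#'
#' Generates a cohort from `spec` (with `seed` substituted), applies the
#' preprocessing rules, builds latest-value/demographic/summary-statistic
#' features and the two patient-by-time-by-feature tensors (quintile edges and
#' all filters fit on the training split only), factorizes the training
#' tensors by non-negative HALS, projects the test patients onto the learned
#' phenotypes, assembles the six feature sets, and reports test-set metrics of
#' a classifier trained per feature set with kNN-imputed features.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (overrides `spec$seed`).
#' @param lv_rank,dxrx_rank Decomposition ranks (default: the planted rank).
#' @param classifier Classifier name (default `"rf"`).
#' @param num_trees Trees for the default forest.
#' @param feature_sets Which of the six sets to evaluate (default all).
#' @return Tibble (feature_set, auroc, auprc, f1, precision, recall) for the
#'   test split; the fitted CP models and feature sets are attached as
#'   attributes `"cp_models"` and `"sets"`.
#' @export
run_phenotyping_pipeline <- function(spec, seed = spec$seed,
                                     lv_rank = NULL, dxrx_rank = NULL,
                                     classifier = "rf", num_trees = 300L,
                                     feature_sets = NULL) {
  spec$seed <- as.integer(seed)
  dat <- generate_cohort(spec)
  cohort <- dat$cohort
  prep <- preprocess_events(dat$events, cohort)
  ev <- prep$events
  train <- cohort[cohort$split == "train", , drop = FALSE]
  test <- cohort[cohort$split == "test", , drop = FALSE]

  latest <- latest_values(ev, cohort)
  demo <- demographic_features(ev, cohort)
  stats <- summary_statistics(ev, cohort)

  var_domain <- ev %>% distinct(.data$variable, .data$domain)
  dx_vars <- intersect(prep$kept_binary,
                       var_domain$variable[var_domain$domain == "dx"])
  rx_vars <- intersect(prep$kept_binary,
                       var_domain$variable[var_domain$domain == "rx"])

  q <- fit_quintiles(ev, train$patient_id, variables = prep$kept_continuous)
  lv_train <- build_labvital_tensor(ev, train, q)
  lv_test <- build_labvital_tensor(ev, test, q)
  dr_train <- build_dxrx_tensor(ev, train, dx_vars, rx_vars)
  dr_test <- build_dxrx_tensor(ev, test, dx_vars, rx_vars)

  lv_model <- nncp_hals(lv_train, rank = lv_rank %||% spec$planted_rank,
                        seed = spec$seed + 10L)
  dr_model <- nncp_hals(dr_train, rank = dxrx_rank %||% spec$planted_rank,
                        seed = spec$seed + 11L)

  lv_mem <- rbind(cp_memberships(lv_model), project_patients(lv_model, lv_test))
  dr_mem <- rbind(cp_memberships(dr_model), project_patients(dr_model, dr_test))
  phen <- phenotype_features(list(labvital = lv_mem, dxrx = dr_mem),
                             cohort$patient_id)

  sets <- assemble_feature_sets(latest, demo, stats, phen)
  if (!is.null(feature_sets)) sets <- sets[feature_sets]
  y <- as.integer(cohort$label == "case")
  tr_rows <- cohort$split == "train"

  res <- purrr::imap_dfr(sets, function(fm, nm) {
    # drop features never observed in the training split, then impute
    obs <- colSums(!is.na(fm[tr_rows, setdiff(names(fm), "patient_id")])) > 0
    keep <- c("patient_id", names(obs)[obs])
    fm <- fm[, keep, drop = FALSE]
    tr_fm <- knn_impute(fm[tr_rows, , drop = FALSE],
                        fm[tr_rows, , drop = FALSE])
    te_fm <- knn_impute(fm[tr_rows, , drop = FALSE],
                        fm[!tr_rows, , drop = FALSE])
    fit <- fit_classifier(classifier, tr_fm, y[tr_rows], seed = spec$seed,
                          params = if (classifier == "rf")
                            list(num_trees = num_trees) else list())
    dplyr::bind_cols(tibble(feature_set = nm),
                     binary_metrics(predict_scores(fit, te_fm), y[!tr_rows]))
  })
  attr(res, "cp_models") <- list(labvital = lv_model, dxrx = dr_model)
  attr(res, "sets") <- sets
  attr(res, "cohort") <- cohort
  res
}

#' Simulate data from a known two-rule fuzzy model
#'
#' Variables are uniform on \[0, 1\]; two planted rules fire through Gaussian
#' concept memberships (width 0.25): rule 1 = "x1 high AND x2 low", rule 2 =
#' "x3 high AND x4 high" (high center 0.8, low center 0.2). A rule's strength
#' is the product of its memberships, rules combine by maximum (fuzzy OR),
#' and the label is 1 when the combined strength exceeds 0.5. Extra noise
#' variables are unused by the rules.
#'
#' @param n Number of samples.
#' @param n_noise Number of uninformative variables (default 2).
#' @param seed Integer seed.
#' @return List with `features` (tibble), `labels` (0/1), and `rules`
#'   (the planted rule definitions).
#' @export
simulate_rule_data <- function(n = 600L, n_noise = 2L, seed = 1L) {
  set.seed(seed)
  V <- 4L + n_noise
  X <- matrix(runif(n * V), n, V)
  colnames(X) <- paste0("x", seq_len(V))
  memb <- function(x, center, width = 0.25) exp(-(x - center)^2 / (2 * width^2))
  s1 <- memb(X[, 1], 0.8) * memb(X[, 2], 0.2)
  s2 <- memb(X[, 3], 0.8) * memb(X[, 4], 0.8)
  labels <- as.integer(pmax(s1, s2) > 0.5)
  rules <- list(list(variables = c("x1", "x2"), concepts = c("high", "low")),
                list(variables = c("x3", "x4"), concepts = c("high", "high")))
  features <- dplyr::bind_cols(tibble(patient_id = sprintf("S%04d", seq_len(n))),
                               as_tibble(X))
  list(features = features, labels = labels, rules = rules)
}
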