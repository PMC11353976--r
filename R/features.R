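# Feature representations: latest values + demographics, five-year summary
# statistics, and the two patient x time x feature tensors that feed the
# non-negative CP decomposition.

#' Construct an EHR tensor
#'
#' A non-negative 3-mode array (patient x time-bin x feature) with axis label
#' registries. Lab/vital tensors hold quintile levels 1-5 with 0 meaning
#' missing-in-bin; dx/rx tensors hold 0/1 presence.
#'
#' @param values Numeric 3-mode array.
#' @param patients,bins,features Axis labels (bins are 0-indexed integers).
#' @param domain `"labvital"` or `"dxrx"`.
#' @return An object of class `ehr_tensor`.
#' @export
ehr_tensor <- function(values, patients, bins, features,
                       domain = c("labvital", "dxrx")) {
  domain <- match.arg(domain)
  stopifnot(length(dim(values)) == 3,
            dim(values)[1] == length(patients),
            dim(values)[2] == length(bins),
            dim(values)[3] == length(features))
  if (any(values < 0) || any(!is.finite(values))) {
    abort("tensor entries must be finite and non-negative")
  }
  dimnames(values) <- list(patients, bins, features)
  structure(list(values = values, patients = patients, bins = bins,
                 features = features, domain = domain),
            class = "ehr_tensor")
}

#' @export
print.ehr_tensor <- function(x, ...) {
  cat("<ehr_tensor>", x$domain, paste(dim(x$values), collapse = " x "),
      "(patient x time x feature)\n")
  invisible(x)
}

#' @export
dim.ehr_tensor <- function(x) dim(x$values)

#' Tidy an EHR tensor into long format
#'
#' @param x An `ehr_tensor`.
#' @param ... Unused.
#' @return Tibble with `patient_id`, `bin`, `feature`, `value`.
#' @method tidy ehr_tensor
#' @export
tidy.ehr_tensor <- function(x, ...) {
  g <- expand.grid(patient_id = x$patients, bin = x$bins, feature = x$features,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g$value <- as.vector(x$values)
  as_tibble(g)
}

provenance_of <- function(fm) attr(fm, "provenance")

set_provenance <- function(fm, tag) {
  prov <- setNames(rep(tag, ncol(fm) - 1L), setdiff(names(fm), "patient_id"))
  attr(fm, "provenance") <- prov
  fm
}

#' Latest recorded value of each continuous variable
#'
#' Per patient and variable, the measurement with the smallest
#' days-before-anchor. Values older than `recency_window` days are set
#' missing.
#'
#' @param events Long event tibble (lab/vital rows used).
#' @param cohort Cohort tibble giving the patient axis and order.
#' @param recency_window Days; default 183.
#' @return A wide tibble (`patient_id` plus one column per variable) with
#'   provenance `"latest"`.
#' @export
latest_values <- function(events, cohort, recency_window = 183L) {
  latest <- events %>%
    filter(.data$domain %in% continuous_domains) %>%
    semi_join(cohort, by = "patient_id") %>%
    arrange(.data$days_before_anchor) %>%
    distinct(.data$patient_id, .data$variable, .keep_all = TRUE) %>%
    filter(.data$days_before_anchor <= recency_window) %>%
    select("patient_id", "variable", "value") %>%
    tidyr::pivot_wider(names_from = "variable", values_from = "value")
  out <- tibble(patient_id = cohort$patient_id) %>%
    left_join(latest, by = "patient_id")
  set_provenance(out, "latest")
}

#' Demographic and family-history features
#'
#' Age, one-hot sex, one-hot demographic categories recorded as `demo` events
#' (e.g. race), and the binary cardiac family-history flag.
#'
#' @param events Long event tibble.
#' @param cohort Cohort tibble with `age` and `sex`.
#' @return Wide tibble with provenance `"demo"`.
#' @export
demographic_features <- function(events, cohort) {
  demo <- events %>%
    filter(.data$domain == "demo") %>%
    semi_join(cohort, by = "patient_id") %>%
    distinct(.data$patient_id, .data$variable) %>%
    mutate(value = 1) %>%
    tidyr::pivot_wider(names_from = "variable", values_from = "value",
                       values_fill = 0)
  fam <- family_history_flag(events, cohort$patient_id)
  out <- tibble(patient_id = cohort$patient_id,
                age = cohort$age,
                sex_M = as.integer(cohort$sex == "M")) %>%
    left_join(fam, by = "patient_id") %>%
    left_join(demo, by = "patient_id")
  out[is.na(out)] <- 0
  set_provenance(out, "demo")
}

#' Five-year summary statistics
#'
#' Mean, sample standard deviation (n - 1 denominator; a single measurement
#' gets SD 0), minimum and maximum per continuous variable, and an
#' ever-present indicator per binary (dx/rx) variable.
#'
#' @param events Long event tibble.
#' @param cohort Cohort tibble giving the patient axis.
#' @return Wide tibble with provenance `"stat"`.
#' @export
summary_statistics <- function(events, cohort) {
  cont <- events %>%
    filter(.data$domain %in% continuous_domains) %>%
    semi_join(cohort, by = "patient_id") %>%
    group_by(.data$patient_id, .data$variable) %>%
    summarise(mean = mean(.data$value),
              sd = ifelse(n() > 1, sd(.data$value), 0),
              min = min(.data$value), max = max(.data$value),
              .groups = "drop") %>%
    tidyr::pivot_longer(c("mean", "sd", "min", "max"),
                        names_to = "stat", values_to = "value") %>%
    mutate(feature = paste0(.data$variable, "_", .data$stat)) %>%
    select("patient_id", "feature", "value") %>%
    tidyr::pivot_wider(names_from = "feature", values_from = "value")
  bin <- events %>%
    filter(.data$domain %in% binary_domains) %>%
    semi_join(cohort, by = "patient_id") %>%
    distinct(.data$patient_id, .data$variable) %>%
    mutate(feature = paste0(.data$variable, "_ever"), value = 1) %>%
    select("patient_id", "feature", "value") %>%
    tidyr::pivot_wider(names_from = "feature", values_from = "value",
                       values_fill = 0)
  out <- tibble(patient_id = cohort$patient_id) %>%
    left_join(cont, by = "patient_id") %>%
    left_join(bin, by = "patient_id")
  evr <- grepl("_ever$", names(out))
  out[evr][is.na(out[evr])] <- 0
  set_provenance(out, "stat")
}

#' Fit quintile edges on training measurements
#'
#' Per-variable 20/40/60/80% quantile edges computed from all training-split
#' measurements. Duplicate edges are collapsed, so a variable with few unique
#' values gets fewer than five levels.
#'
#' @param events Long event tibble (lab/vital rows).
#' @param train_ids Training-split patient ids.
#' @param variables Variables to fit (default: all present).
#' @return Named list of numeric edge vectors.
#' @export
fit_quintiles <- function(events, train_ids, variables = NULL) {
  cont <- events %>%
    filter(.data$domain %in% continuous_domains,
           .data$patient_id %in% train_ids)
  if (is.null(variables)) variables <- sort(unique(cont$variable))
  lapply(setNames(variables, variables), function(v) {
    vals <- cont$value[cont$variable == v]
    if (length(vals) == 0) return(numeric(0))
    unique(unname(quantile(vals, probs = c(0.2, 0.4, 0.6, 0.8))))
  })
}

# Level assignment: level 1 covers values <= first edge, intervals are
# (edge_i, edge_{i+1}], the top level is open above.
quintile_level <- function(x, edges) {
  if (length(edges) == 0) return(rep(1L, length(x)))
  findInterval(x, edges, left.open = TRUE) + 1L
}

#' Build the lab/vital tensor
#'
#' Ten six-month anchor-relative bins; only the last recorded value of each
#' variable per bin is kept, then discretized into training-set quintile
#' levels 1-5. Empty patient-bin-variable cells are 0 (missing-in-bin).
#'
#' @param events Long event tibble.
#' @param cohort Cohort tibble giving the patient axis and order.
#' @param quintiles Edges from [fit_quintiles()] (fit on train only). Its
#'   names define the feature axis.
#' @param n_bins Number of bins (default 10).
#' @param discretize If `FALSE`, keep raw last values (used for recovery
#'   diagnostics on noiseless synthetic data).
#' @return An `ehr_tensor` with domain `"labvital"`.
#' @export
build_labvital_tensor <- function(events, cohort, quintiles, n_bins = 10L,
                                  discretize = TRUE) {
  vars <- names(quintiles)
  pats <- cohort$patient_id
  ev <- events %>%
    filter(.data$domain %in% continuous_domains, .data$variable %in% vars) %>%
    semi_join(cohort, by = "patient_id") %>%
    mutate(bin = bin_of_days(.data$days_before_anchor, n_bins = n_bins)) %>%
    filter(!is.na(.data$bin)) %>%
    arrange(.data$days_before_anchor) %>%            # last value in the bin
    distinct(.data$patient_id, .data$variable, .data$bin, .keep_all = TRUE)
  arr <- array(0, c(length(pats), n_bins, length(vars)))
  pi <- match(ev$patient_id, pats)
  vi <- match(ev$variable, vars)
  val <- ev$value
  if (discretize) {
    for (v in seq_along(vars)) {
      sel <- vi == v
      val[sel] <- quintile_level(val[sel], quintiles[[vars[v]]])
    }
  }
  arr[cbind(pi, ev$bin + 1L, vi)] <- val
  ehr_tensor(arr, pats, 0:(n_bins - 1L), vars, domain = "labvital")
}

#' Build the diagnosis/medication tensor
#'
#' Diagnoses: per-bin presence recorded only in bins with an encounter;
#' encounter-free bins inherit the previous bin's value (carry-forward) and
#' any remaining gaps are zero-filled. Medications: per-bin prescription flag,
#' zero-filled, no carry-forward.
#'
#' @param events Long event tibble.
#' @param cohort Cohort tibble giving the patient axis and order.
#' @param dx_vars,rx_vars Feature lists (fit/filtered upstream).
#' @param n_bins Number of bins (default 10).
#' @return An `ehr_tensor` with domain `"dxrx"` and entries in {0, 1}.
#' @export
build_dxrx_tensor <- function(events, cohort, dx_vars, rx_vars, n_bins = 10L) {
  pats <- cohort$patient_id
  np <- length(pats)
  ev <- events %>%
    semi_join(cohort, by = "patient_id") %>%
    mutate(bin = bin_of_days(.data$days_before_anchor, n_bins = n_bins)) %>%
    filter(!is.na(.data$bin))
  # encounter = any visit-generating record (labs, vitals, diagnoses)
  enc <- matrix(FALSE, np, n_bins)
  vis <- ev %>% filter(.data$domain %in% c(continuous_domains, "dx")) %>%
    distinct(.data$patient_id, .data$bin)
  enc[cbind(match(vis$patient_id, pats), vis$bin + 1L)] <- TRUE

  arr <- array(0, c(np, n_bins, length(dx_vars) + length(rx_vars)))
  dx <- ev %>% filter(.data$domain == "dx", .data$variable %in% dx_vars) %>%
    distinct(.data$patient_id, .data$variable, .data$bin)
  for (f in seq_along(dx_vars)) {
    m <- matrix(NA_real_, np, n_bins)
    m[enc] <- 0
    rows <- dx[dx$variable == dx_vars[f], , drop = FALSE]
    m[cbind(match(rows$patient_id, pats), rows$bin + 1L)] <- 1
    for (t in 2:n_bins) {
      gap <- is.na(m[, t])
      m[gap, t] <- m[gap, t - 1L]
    }
    m[is.na(m)] <- 0
    arr[, , f] <- m
  }
  rx <- ev %>% filter(.data$domain == "rx", .data$variable %in% rx_vars) %>%
    distinct(.data$patient_id, .data$variable, .data$bin)
  for (f in seq_along(rx_vars)) {
    rows <- rx[rx$variable == rx_vars[f], , drop = FALSE]
    m <- matrix(0, np, n_bins)
    m[cbind(match(rows$patient_id, pats), rows$bin + 1L)] <- 1
    arr[, , length(dx_vars) + f] <- m
  }
  ehr_tensor(arr, pats, 0:(n_bins - 1L), c(dx_vars, rx_vars), domain = "dxrx")
}

#' Bins overlapped by a prescription interval
#'
#' Maps a prescription active from `from_days` to `to_days` before the anchor
#' (inclusive) to the 0-indexed six-month bins it overlaps.
#'
#' @param from_days Older end of the interval (days before anchor).
#' @param to_days Newer end (days before anchor, `<= from_days`).
#' @param n_bins,bin_days Binning as in [bin_of_days()].
#' @return Integer vector of overlapped bins.
#' @export
rx_bins_from_interval <- function(from_days, to_days = 0L, n_bins = 10L,
                                  bin_days = 183L) {
  stopifnot(from_days >= to_days)
  from_days <- min(from_days, n_bins * bin_days - 1L)
  lo <- bin_of_days(from_days, n_bins, bin_days)
  hi <- bin_of_days(to_days, n_bins, bin_days)
  lo:hi
}

#' Assemble the six evaluated feature sets
#'
#' The three sources (latest values + demographics, summary statistics,
#' phenotype memberships) and their combinations:
#' latest/demographics; statistics; phenotypes; latest + statistics;
#' latest + phenotypes; and all three ("all").
#'
#' @param latest,demo,stats,phen Wide feature tibbles sharing an identical
#'   `patient_id` axis.
#' @return Named list of six feature tibbles, provenance tags preserved.
#' @export
assemble_feature_sets <- function(latest, demo, stats, phen) {
  mats <- list(latest = latest, demo = demo, stats = stats, phen = phen)
  ids <- latest$patient_id
  for (nm in names(mats)) {
    if (!identical(mats[[nm]]$patient_id, ids)) {
      abort(paste0("patient axis of `", nm, "` does not match `latest`"))
    }
  }
  cbind_fm <- function(...) {
    parts <- list(...)
    out <- purrr::reduce(parts, function(a, b) {
      dup <- intersect(setdiff(names(b), "patient_id"), names(a))
      if (length(dup)) abort(paste0("duplicate feature names: ",
                                    paste(dup, collapse = ", ")))
      dplyr::bind_cols(a, select(b, -"patient_id"))
    })
    attr(out, "provenance") <- do.call(c, lapply(parts, provenance_of))
    out
  }
  ld <- cbind_fm(latest, demo)
  list(
    latest_demo = ld,
    statistics = stats,
    phenotypes = phen,
    latest_demo_statistics = cbind_fm(latest, demo, stats),
    latest_demo_phenotypes = cbind_fm(latest, demo, phen),
    all = cbind_fm(latest, demo, stats, phen)
  )
}
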