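# Cleaning, encoding, hierarchy and filtering rules for long-format EHR
# events. All data-dependent filters are fit on the training split only and
# the resulting kept-variable lists are then frozen and applied to both
# splits.

#' Cleaning and filtering configuration
#'
#' @param ranges Tibble with columns `variable`, `min`, `max`: plausible
#'   ranges for numeric variables. Values outside the range are dropped.
#'   Variables not listed are kept unchecked.
#' @param temperature_vars Variables holding body temperature. Values at or
#'   below `celsius_max` are taken to be Celsius and converted to Fahrenheit
#'   (F = C * 9/5 + 32); body temperature in the two scales does not overlap.
#' @param celsius_max Threshold separating Celsius from Fahrenheit entries.
#' @param missingness_cutoff Continuous variables are kept only if the
#'   fraction of training patients with at least one measurement is strictly
#'   greater than this.
#' @param prevalence_cutoff Binary variables are dropped if present in
#'   strictly less than this fraction of both case and control training
#'   patients.
#' @param recency_window Days before the anchor within which a "latest value"
#'   still counts (default 183, a six-month window).
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(ranges = NULL,
                            temperature_vars = "temperature",
                            celsius_max = 45,
                            missingness_cutoff = 0.60,
                            prevalence_cutoff = 0.01,
                            recency_window = 183L) {
  if (missingness_cutoff <= 0 || missingness_cutoff >= 1 ||
      prevalence_cutoff <= 0 || prevalence_cutoff >= 1) {
    abort("cutoffs must lie strictly in (0, 1)")
  }
  if (!is.null(ranges)) {
    stopifnot(all(c("variable", "min", "max") %in% names(ranges)))
    if (any(ranges$min >= ranges$max)) abort("ranges must have min < max")
  }
  structure(list(ranges = ranges, temperature_vars = temperature_vars,
                 celsius_max = celsius_max,
                 missingness_cutoff = missingness_cutoff,
                 prevalence_cutoff = prevalence_cutoff,
                 recency_window = as.integer(recency_window)),
            class = "cleaning_config")
}

continuous_domains <- c("lab", "vital")
binary_domains <- c("dx", "rx")

#' Clean numeric event values
#'
#' Drops rows in continuous domains (lab, vital) whose value does not parse as
#' a number or falls outside the configured plausible range, and converts
#' Celsius temperature entries to Fahrenheit. Rows in other domains pass
#' through untouched. Dropped-row counts are attached as the `"dropped"`
#' attribute.
#'
#' @param events Long event tibble.
#' @param config A [cleaning_config()].
#' @return The cleaned events, `value` numeric for continuous domains.
#' @export
clean_values <- function(events, config = cleaning_config()) {
  cont <- events$domain %in% continuous_domains
  out <- events
  out$value <- suppressWarnings(as.numeric(out$value))
  unparsable <- cont & is.na(out$value) & !is.na(events$value)
  out <- out[!unparsable, , drop = FALSE]
  cont <- out$domain %in% continuous_domains

  is_temp <- cont & out$variable %in% config$temperature_vars &
    !is.na(out$value) & out$value <= config$celsius_max
  out$value[is_temp] <- out$value[is_temp] * 9 / 5 + 32

  out_of_range <- rep(FALSE, nrow(out))
  if (!is.null(config$ranges)) {
    m <- match(out$variable, config$ranges$variable)
    has_range <- cont & !is.na(m)
    out_of_range[has_range] <-
      out$value[has_range] < config$ranges$min[m[has_range]] |
      out$value[has_range] > config$ranges$max[m[has_range]]
  }
  res <- out[!out_of_range, , drop = FALSE]
  attr(res, "dropped") <- c(unparsable = sum(unparsable),
                            out_of_range = sum(out_of_range))
  res
}

#' Convert ICD-9 diagnosis codes to ICD-10
#'
#' Diagnosis codes starting with a digit are treated as ICD-9 and replaced via
#' the two-column mapping; ICD-9 codes absent from the mapping are dropped
#' (mixing vocabularies would corrupt the hierarchy roll-up). Letter-leading
#' (ICD-10) codes pass through unchanged. The dropped count is attached as the
#' `"dropped"` attribute.
#'
#' @param events Long event tibble.
#' @param mapping Tibble with columns `icd9`, `icd10`, or a path to such a
#'   TSV. [icd9_to_icd10_synthetic()] ships a small synthetic mapping.
#' @return Events with dx codes in ICD-10.
#' @export
map_icd9_to_icd10 <- function(events, mapping) {
  if (is.character(mapping)) {
    mapping <- as_tibble(utils::read.delim(mapping, sep = "\t",
                                           colClasses = "character"))
  }
  if (!all(c("icd9", "icd10") %in% names(mapping))) {
    abort("mapping must have columns `icd9` and `icd10`")
  }
  is9 <- events$domain == "dx" & grepl("^[0-9]", events$variable)
  m <- match(events$variable, mapping$icd9)
  mapped <- is9 & !is.na(m)
  out <- events
  out$variable[mapped] <- mapping$icd10[m[mapped]]
  drop <- is9 & is.na(m)
  res <- out[!drop, , drop = FALSE]
  attr(res, "dropped") <- c(unmapped_icd9 = sum(drop))
  res
}

#' Synthetic ICD-9 to ICD-10 mapping table
#'
#' A small synthetic two-column conversion table; any real conversion table
#' with columns `icd9` and `icd10` can be plugged in instead.
#' @return Tibble with columns `icd9`, `icd10`.
#' @export
icd9_to_icd10_synthetic <- function() {
  path <- system.file("extdata", "synthetic_icd9_to_icd10.tsv",
                      package = "tempheno")
  as_tibble(utils::read.delim(path, sep = "\t", colClasses = "character"))
}

#' Remove chapter-Z ICD-10 codes
#'
#' Chapter Z ("factors influencing health status and contact with health
#' services") carries administrative rather than clinical content.
#'
#' @param events Long event tibble.
#' @return Events without dx codes starting with "Z".
#' @export
drop_z_chapter <- function(events) {
  keep <- !(events$domain == "dx" & startsWith(toupper(events$variable), "Z"))
  events[keep, , drop = FALSE]
}

#' Roll diagnosis codes up to their 3-character category
#'
#' For every dx event whose code extends beyond the 3-character ICD-10
#' category (e.g. `E11.0` or `E1165`), an event for the category (`E11`) is
#' also emitted at the same timestamp. Idempotent and monotone: it only adds
#' category events, never removes or duplicates rows.
#'
#' @param events Long event tibble (non-dx rows pass through).
#' @return Events plus rolled-up category events.
#' @export
rollup_hierarchy <- function(events) {
  dx <- events[events$domain == "dx", , drop = FALSE]
  if (nrow(dx) == 0) return(events)
  bare <- gsub(".", "", dx$variable, fixed = TRUE)
  child <- nchar(bare) > 3
  if (!any(child)) return(events)
  parents <- dx[child, , drop = FALSE]
  parents$variable <- substr(bare[child], 1, 3)
  parents <- distinct(parents)
  out <- distinct(bind_rows(events, parents))
  arrange(out, .data$patient_id, .data$days_before_anchor,
          .data$domain, .data$variable)
}

#' Keep continuous variables measured in enough training patients
#'
#' A variable is kept iff the fraction of training patients with at least one
#' measurement is strictly greater than `missingness_cutoff` (default 0.60).
#' The returned list is meant to be frozen and applied to both splits.
#'
#' @param events Long event tibble (only lab/vital rows are considered).
#' @param train_ids Character vector of training-split patient ids (the
#'   denominator; patients with no events count as unmeasured).
#' @param config A [cleaning_config()].
#' @return Character vector of kept variable names.
#' @export
missingness_filter <- function(events, train_ids, config = cleaning_config()) {
  if (length(train_ids) == 0) abort("empty training split")
  cont <- events %>%
    filter(.data$domain %in% continuous_domains,
           .data$patient_id %in% train_ids)
  frac <- cont %>%
    distinct(.data$patient_id, .data$variable) %>%
    dplyr::count(.data$variable) %>%
    mutate(frac = .data$n / length(train_ids))
  sort(frac$variable[frac$frac > config$missingness_cutoff])
}

#' Keep binary variables prevalent in cases or controls
#'
#' A binary variable (dx/rx) is dropped iff its training-set prevalence is
#' strictly below `prevalence_cutoff` (default 1%) in *both* cases and
#' controls.
#'
#' @param events Long event tibble (dx/rx rows considered).
#' @param train_cohort Cohort tibble for the training split with `patient_id`
#'   and `label` ("case"/"control").
#' @param config A [cleaning_config()].
#' @return Character vector of kept variable names.
#' @export
prevalence_filter <- function(events, train_cohort, config = cleaning_config()) {
  for (cl in c("case", "control")) {
    if (!any(train_cohort$label == cl)) abort(paste0("no ", cl, "s in training split"))
  }
  n_by_class <- table(train_cohort$label)
  pres <- events %>%
    filter(.data$domain %in% binary_domains) %>%
    semi_join(train_cohort, by = "patient_id") %>%
    distinct(.data$patient_id, .data$variable) %>%
    left_join(select(train_cohort, "patient_id", "label"), by = "patient_id") %>%
    dplyr::count(.data$variable, .data$label) %>%
    mutate(prev = .data$n / as.numeric(n_by_class[as.character(.data$label)]))
  wide <- pres %>%
    select("variable", "label", "prev") %>%
    tidyr::pivot_wider(names_from = "label", values_from = "prev",
                       values_fill = 0)
  if (!"case" %in% names(wide)) wide$case <- 0
  if (!"control" %in% names(wide)) wide$control <- 0
  keep <- wide$case >= config$prevalence_cutoff |
    wide$control >= config$prevalence_cutoff
  sort(wide$variable[keep])
}

#' Binary cardiac family-history flag
#'
#' @param events Long event tibble; famhx rows carry a condition name in
#'   `variable`.
#' @param patient_ids Patients to flag (patients without qualifying history
#'   get 0).
#' @param qualifying Character vector of qualifying condition names
#'   (default [cardiac_family_history_terms()]).
#' @return Tibble with `patient_id` and `family_history` in {0, 1}.
#' @export
family_history_flag <- function(events, patient_ids,
                                qualifying = cardiac_family_history_terms()) {
  hits <- events %>%
    filter(.data$domain == "famhx",
           tolower(.data$variable) %in% tolower(qualifying)) %>%
    distinct(.data$patient_id)
  tibble(patient_id = patient_ids,
         family_history = as.integer(patient_ids %in% hits$patient_id))
}

#' Carry-forward then zero imputation of an interval sequence
#'
#' `NA`s following an observed value take the last observed value; leading
#' `NA`s (before any observation) become 0.
#'
#' @param x Numeric vector with `NA` for encounter-free intervals.
#' @return Imputed vector of the same length.
#' @export
carry_forward_zero <- function(x) {
  out <- zoo::na.locf(x, na.rm = FALSE)
  out[is.na(out)] <- 0
  out
}

#' Composed preprocessing pipeline
#'
#' Applies, in order: value cleaning, ICD-9 to ICD-10 mapping, chapter-Z
#' removal, 3-character hierarchy roll-up, then the train-fitted missingness
#' and prevalence filters (frozen and applied to both splits). Re-running the
#' pipeline on its own output is a no-op.
#'
#' @param events Long event tibble.
#' @param cohort Cohort tibble with `patient_id`, `label`, `split`.
#' @param config A [cleaning_config()].
#' @param icd9_map Two-column ICD-9/ICD-10 mapping (default the synthetic one).
#' @return A list with `events` (filtered to kept variables; famhx/demo rows
#'   retained), `kept_continuous`, `kept_binary`, and `log` (dropped counts).
#' @export
preprocess_events <- function(events, cohort, config = cleaning_config(),
                              icd9_map = icd9_to_icd10_synthetic()) {
  cleaned <- clean_values(events, config)
  log1 <- attr(cleaned, "dropped")
  mapped <- map_icd9_to_icd10(cleaned, icd9_map)
  log2 <- attr(mapped, "dropped")
  nz <- drop_z_chapter(mapped)
  rolled <- rollup_hierarchy(nz)

  train_ids <- cohort$patient_id[cohort$split == "train"]
  kept_cont <- missingness_filter(rolled, train_ids, config)
  kept_bin <- prevalence_filter(rolled,
                                cohort[cohort$split == "train", , drop = FALSE],
                                config)
  keep_row <- (rolled$domain %in% continuous_domains &
                 rolled$variable %in% kept_cont) |
    (rolled$domain %in% binary_domains & rolled$variable %in% kept_bin) |
    !(rolled$domain %in% c(continuous_domains, binary_domains))
  list(events = rolled[keep_row, , drop = FALSE],
       kept_continuous = kept_cont,
       kept_binary = kept_bin,
       log = c(log1, log2,
               dropped_z = sum(mapped$domain == "dx") - sum(nz$domain == "dx")))
}
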