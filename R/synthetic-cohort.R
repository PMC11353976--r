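# Synthetic longitudinal EHR cohorts with planted low-rank temporal phenotypes.
#
# The generator emulates the statistical shape of an outpatient EHR extract:
# irregular encounter times, continuous labs/vitals with missingness, binary
# diagnosis/medication events with ICD-10-like hierarchical codes, family
# history and demographics, 2:1 matched controls, and outcomes driven by
# planted low-rank patient-by-time-by-feature structure so that downstream
# tensor decompositions have a known ground truth to recover.

#' Specify a synthetic EHR cohort
#'
#' Collects and validates the parameters of the synthetic-cohort generator.
#' Defaults describe the study conditions used throughout the package's tests:
#' a five-year observation window, roughly 2000 patients in 2:1 matched
#' case-control sets, a planted rank-4 temporal signal, and an outcome whose
#' log-odds load on the first phenotype membership.
#'
#' @param n_cases Number of case patients to aim for after matching.
#' @param control_ratio Controls matched to each case.
#' @param years Observation span in years before the anchor date.
#' @param n_lab_features,n_dx_features,n_rx_features Feature counts per domain.
#' @param planted_rank Rank of the planted low-rank temporal signal.
#' @param encounter_rate Mean outpatient encounters per patient per year.
#' @param missing_prob Probability that a lab is unmeasured at an encounter.
#' @param outcome_coefs Per-phenotype log-odds effects on the outcome; length
#'   must equal `planted_rank`.
#' @param noise_sd Gaussian noise SD added to lab values (signal scale is
#'   roughly 1).
#' @param seed Integer seed; identical specs give byte-identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 667L,
                        control_ratio = 2L,
                        years = 5,
                        n_lab_features = 12L,
                        n_dx_features = 15L,
                        n_rx_features = 8L,
                        planted_rank = 4L,
                        encounter_rate = 8,
                        missing_prob = 0.3,
                        outcome_coefs = c(1.5, rep(0, planted_rank - 1)),
                        noise_sd = 0.5,
                        seed = 1L) {
  counts <- c(n_cases = n_cases, control_ratio = control_ratio,
              n_lab_features = n_lab_features, n_dx_features = n_dx_features,
              n_rx_features = n_rx_features, planted_rank = planted_rank)
  if (any(counts < 1)) {
    abort(paste0("all counts must be >= 1; offending: ",
                 paste(names(counts)[counts < 1], collapse = ", ")))
  }
  if (years <= 0) abort("`years` must be > 0")
  if (missing_prob < 0 || missing_prob > 1) abort("`missing_prob` must be in [0, 1]")
  if (encounter_rate <= 0) abort("`encounter_rate` must be > 0")
  if (planted_rank > min(n_lab_features, n_dx_features + n_rx_features)) {
    abort("`planted_rank` may not exceed the smallest feature count")
  }
  if (length(outcome_coefs) != planted_rank) {
    abort("`outcome_coefs` must have length `planted_rank`")
  }
  structure(
    list(n_cases = as.integer(n_cases), control_ratio = as.integer(control_ratio),
         years = years, n_lab_features = as.integer(n_lab_features),
         n_dx_features = as.integer(n_dx_features),
         n_rx_features = as.integer(n_rx_features),
         planted_rank = as.integer(planted_rank),
         encounter_rate = encounter_rate, missing_prob = missing_prob,
         outcome_coefs = as.numeric(outcome_coefs), noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_cases, "cases, 1:", x$control_ratio,
      "matching,", x$years, "years, planted rank", x$planted_rank, "\n")
  invisible(x)
}

# ICD-10-like code pools used by the generator. Non-Z chapters only (the
# preprocessing pipeline drops chapter Z), with subcodes so the 3-character
# roll-up is exercised end to end.
synthetic_dx_codes <- function(n) {
  stems <- c("E11", "I10", "E78", "M54", "G89", "J45", "K21", "F32", "N18",
             "M25", "D64", "G47", "L40", "H52", "B20", "C50", "A09", "E66",
             "I83", "K58", "M17", "N39", "R51", "E03", "J30")
  stems <- rep_len(stems, n)
  paste0(stems, ".", (seq_len(n) - 1L) %% 9L)
}

synthetic_rx_codes <- function(n) {
  meds <- c("atorvastatin", "lisinopril", "metformin", "amlodipine",
            "ibuprofen", "omeprazole", "sertraline", "albuterol",
            "clopidogrel", "levothyroxine", "gabapentin", "losartan")
  rep_len(paste0("rx_", meds), n)[seq_len(n)]
}

# Smooth non-negative time profiles over `n_bins` bins, peaking away from the
# anchor for most components so the planted signal is genuinely historical.
planted_time_profiles <- function(n_bins, rank) {
  centers <- seq(2, n_bins - 2, length.out = rank)
  B <- sapply(seq_len(rank), function(r) {
    b <- exp(-((seq_len(n_bins) - centers[r])^2) / (2 * 1.5^2))
    b / max(b)
  })
  matrix(B, nrow = n_bins, ncol = rank)
}

# Feature profiles: each feature loads strongly on one component plus a small
# dense background, keeping components distinguishable but overlapping.
planted_feature_profiles <- function(n_features, rank) {
  C <- matrix(runif(n_features * rank, 0, 0.15), n_features, rank)
  main <- rep_len(seq_len(rank), n_features)
  C[cbind(seq_len(n_features), main)] <- runif(n_features, 0.7, 1.3)
  C
}

#' Assign outcome labels from phenotype memberships
#'
#' Labels are Bernoulli draws with logit `intercept + memberships %*% coefs`;
#' the intercept is solved numerically so the expected prevalence equals
#' `target_prevalence` (by default `1 / (1 + control_ratio)` upstream).
#'
#' @param memberships Non-negative numeric matrix, patients by phenotypes.
#' @param outcome_coefs Log-odds effect per phenotype column.
#' @param seed Integer seed for the Bernoulli draws.
#' @param target_prevalence Desired expected case fraction.
#' @return Integer vector of 0/1 labels with the solved intercept in
#'   `attr(, "intercept")`.
#' @export
assign_outcomes <- function(memberships, outcome_coefs, seed,
                            target_prevalence = 1 / 3) {
  memberships <- as.matrix(memberships)
  if (any(memberships < 0)) abort("`memberships` must be non-negative")
  if (length(outcome_coefs) != ncol(memberships)) {
    abort("`outcome_coefs` length must equal the number of membership columns")
  }
  eta <- drop(memberships %*% outcome_coefs)
  f <- function(b) mean(plogis(b + eta)) - target_prevalence
  intercept <- uniroot(f, c(-30, 30))$root
  p <- plogis(intercept + eta)
  set.seed(seed)
  labels <- rbinom(length(p), 1L, p)
  attr(labels, "intercept") <- intercept
  labels
}

#' Hospital-frailty-style score from diagnosis history
#'
#' Sums the weights of the *distinct* mapped diagnosis codes in a patient's
#' history; codes absent from the weight map contribute zero. The weight map is
#' pluggable; [frailty_weights_synthetic()] ships a small synthetic table keyed
#' by 3-character ICD-10 categories.
#'
#' @param dx_events Tibble with columns `patient_id` and `variable` (codes).
#' @param weight_map Tibble with columns `code` and `weight`.
#' @return Tibble with `patient_id` and `frailty` (patients with no mapped
#'   diagnoses score 0 and are retained).
#' @export
frailty_score <- function(dx_events, weight_map) {
  if (!all(c("code", "weight") %in% names(weight_map))) {
    abort("`weight_map` needs columns `code` and `weight`")
  }
  if (nrow(dx_events) == 0) {
    return(tibble(patient_id = character(), frailty = numeric()))
  }
  dx_events %>%
    distinct(.data$patient_id, .data$variable) %>%
    left_join(weight_map, by = c(variable = "code")) %>%
    mutate(weight = dplyr::coalesce(.data$weight, 0)) %>%
    group_by(.data$patient_id) %>%
    summarise(frailty = sum(.data$weight), .groups = "drop")
}

#' Synthetic frailty weight table
#'
#' A small synthetic stand-in for a published hospital-frailty weight
#' catalogue, keyed by 3-character ICD-10 categories. Any real weight table
#' with columns `code` and `weight` can be supplied in its place.
#'
#' @return Tibble with columns `code` and `weight`.
#' @export
frailty_weights_synthetic <- function() {
  path <- system.file("extdata", "synthetic_frailty_weights.tsv",
                      package = "tempheno")
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Match controls to cases without replacement
#'
#' Greedy nearest-first matching: cases are processed in ascending
#' `patient_id`; each receives `ratio` controls matching exactly on sex and
#' within `age_tol` years of age and `frailty_tol` points of frailty, chosen
#' nearest by |age difference|, ties broken by |frailty difference| then
#' `patient_id`. Cases that cannot be given a full set of controls are
#' excluded, and no control is reused.
#'
#' @param candidates Tibble with `patient_id`, `label` ("case"/"control"),
#'   `sex`, `age`, `frailty`.
#' @param ratio Controls per case.
#' @param age_tol,frailty_tol Matching tolerances (years / points).
#' @return The matched subset of `candidates` with a `matched_set_id` column;
#'   each set holds one case and `ratio` controls.
#' @export
match_controls <- function(candidates, ratio = 2L, age_tol = 2, frailty_tol = 2) {
  if (ratio < 1) abort("`ratio` must be >= 1")
  if (nrow(candidates) == 0) abort("empty candidate pool")
  cases <- candidates %>% filter(.data$label == "case") %>%
    arrange(.data$patient_id)
  ctrl <- candidates %>% filter(.data$label == "control")
  taken <- logical(nrow(ctrl))
  out <- vector("list", nrow(cases))
  set_id <- 0L
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    ok <- !taken & ctrl$sex == cs$sex &
      abs(ctrl$age - cs$age) <= age_tol &
      abs(ctrl$frailty - cs$frailty) <= frailty_tol
    idx <- which(ok)
    if (length(idx) < ratio) next
    ord <- order(abs(ctrl$age[idx] - cs$age),
                 abs(ctrl$frailty[idx] - cs$frailty),
                 ctrl$patient_id[idx])
    pick <- idx[ord[seq_len(ratio)]]
    taken[pick] <- TRUE
    set_id <- set_id + 1L
    out[[set_id]] <- bind_rows(cs, ctrl[pick, ]) %>%
      mutate(matched_set_id = set_id)
  }
  if (set_id == 0L) {
    return(candidates[0, ] %>% mutate(matched_set_id = integer()))
  }
  bind_rows(out[seq_len(set_id)])
}

#' Generate a synthetic matched EHR cohort
#'
#' Draws a patient pool with demographics and planted phenotype memberships,
#' simulates five years of irregular outpatient encounters with lab values
#' (low-rank signal plus Gaussian noise, missing at random), diagnosis and
#' medication presence (Bernoulli with a logit-linear low-rank intensity,
#' recorded only at encounters), family history and demographic events;
#' computes frailty scores from the diagnosis stream, assigns outcomes from the
#' planted memberships, matches controls to cases, and splits matched sets
#' 70/30 into train and test.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `events` (long event tibble with columns `patient_id`,
#'   `days_before_anchor`, `domain`, `variable`, `value`), `cohort` (one row
#'   per matched patient: label, age, sex, frailty, matched_set_id, split), and
#'   `phenotypes` (the planted ground truth: per component, the patient
#'   loadings over the returned patients, the 10-bin time profile, and the lab
#'   and dx/rx feature profiles).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_bins <- 10L
  bin_days <- 183
  window_days <- floor(365 * spec$years)
  # candidate pool oversampled so greedy matching can fill every set; the
  # constant headroom matters for small cohorts where eligible controls are
  # scarce by chance
  pool_n <- ceiling(spec$n_cases * (1 + spec$control_ratio) * 1.7) + 150L
  pid <- sprintf("P%05d", seq_len(pool_n))

  age <- pmin(89L, pmax(23L, round(rnorm(pool_n, 63, 13))))
  sex <- sample(c("M", "F"), pool_n, replace = TRUE, prob = c(0.55, 0.45))
  race <- sample(c("white", "black", "asian", "other"), pool_n,
                 replace = TRUE, prob = c(0.82, 0.08, 0.05, 0.05))

  R <- spec$planted_rank
  A <- matrix(rgamma(pool_n * R, shape = 2, rate = 2), pool_n, R)
  B <- planted_time_profiles(n_bins, R)
  C_lab <- planted_feature_profiles(spec$n_lab_features, R)
  n_dxrx <- spec$n_dx_features + spec$n_rx_features
  C_dxrx <- planted_feature_profiles(n_dxrx, R)

  lab_names <- sprintf("lab_%02d", seq_len(spec$n_lab_features))
  dx_names <- synthetic_dx_codes(spec$n_dx_features)
  rx_names <- synthetic_rx_codes(spec$n_rx_features)

  # Encounters: Poisson count (floor 3, mirroring a minimum-visit inclusion
  # rule), days uniform over the window.
  n_enc <- pmax(3L, rpois(pool_n, spec$encounter_rate * spec$years))
  enc <- tibble(
    patient_id = rep(pid, n_enc),
    days_before_anchor = unlist(lapply(n_enc, function(k) {
      sort(sample.int(window_days, k, replace = TRUE) - 1L)
    }))
  )
  # bin is 0-indexed with bin (n_bins - 1) adjacent to the anchor
  enc$bin <- bin_of_days(enc$days_before_anchor, n_bins = n_bins, bin_days = bin_days)

  pat_index <- setNames(seq_len(pool_n), pid)

  # Lab events at encounters: signal A B C + noise, one row per measured lab.
  n_enc_rows <- nrow(enc)
  keep <- matrix(runif(n_enc_rows * spec$n_lab_features) >= spec$missing_prob,
                 n_enc_rows, spec$n_lab_features)
  ABt <- A[pat_index[enc$patient_id], , drop = FALSE] *
    B[enc$bin + 1L, , drop = FALSE]           # rowwise A_i * B_bin
  signal <- ABt %*% t(C_lab)                  # encounters x labs
  noise <- matrix(rnorm(n_enc_rows * spec$n_lab_features, 0, spec$noise_sd),
                  n_enc_rows, spec$n_lab_features)
  vals <- pmax(signal + noise, 0)
  meas <- which(keep, arr.ind = TRUE)
  lab_events <- tibble(
    patient_id = enc$patient_id[meas[, 1]],
    days_before_anchor = enc$days_before_anchor[meas[, 1]],
    domain = "lab",
    variable = lab_names[meas[, 2]],
    value = vals[meas]
  )

  # Dx/Rx presence per patient x bin with a logit-linear low-rank intensity,
  # recorded only in bins that contain an encounter (dx) or at all (rx, since
  # prescriptions span intervals independent of visits).
  # presence[i, t, f] ~ Bernoulli(plogis(logit0 + 2 * sum_r A[i,r] B[t,r] C[f,r]))
  make_presence <- function(C_block) {
    nf <- nrow(C_block)
    pres <- vector("list", nf)
    for (f in seq_len(nf)) {
      AC <- sweep(A, 2, C_block[f, ], "*")
      eta <- qlogis(0.06) + 2 * AC %*% t(B)   # pool_n x n_bins
      pres[[f]] <- matrix(runif(pool_n * n_bins) < plogis(eta), pool_n, n_bins)
    }
    pres
  }
  dx_pres <- make_presence(C_dxrx[seq_len(spec$n_dx_features), , drop = FALSE])
  rx_pres <- make_presence(
    C_dxrx[spec$n_dx_features + seq_len(spec$n_rx_features), , drop = FALSE])

  enc_day_in_bin <- enc %>%
    group_by(.data$patient_id, .data$bin) %>%
    slice(1) %>% ungroup()
  edb <- enc_day_in_bin
  edb_key <- paste(edb$patient_id, edb$bin)
  edb_day <- setNames(edb$days_before_anchor, edb_key)

  presence_events <- function(pres, names_vec, domain, need_encounter) {
    rows <- vector("list", length(pres))
    for (f in seq_along(pres)) {
      hit <- which(pres[[f]], arr.ind = TRUE)
      if (nrow(hit) == 0) next
      p <- pid[hit[, 1]]
      b <- hit[, 2] - 1L
      if (need_encounter) {
        day <- edb_day[paste(p, b)]
        ok <- !is.na(day)
        p <- p[ok]; b <- b[ok]; day <- unname(day[ok])
      } else {
        # mid-bin day for interval-style records
        day <- pmin(window_days - 1L,
                    (n_bins - 1L - b) * bin_days + bin_days %/% 2L)
      }
      if (length(p) == 0) next
      rows[[f]] <- tibble(patient_id = p, days_before_anchor = as.integer(day),
                          domain = domain, variable = names_vec[f], value = 1)
    }
    bind_rows(rows)
  }
  dx_events <- presence_events(dx_pres, dx_names, "dx", need_encounter = TRUE)
  rx_events <- presence_events(rx_pres, rx_names, "rx", need_encounter = FALSE)

  # Family history and demographics (time-independent; recorded at day 0).
  qualifying <- cardiac_family_history_terms()
  other_conditions <- c("asthma", "depression", "arthritis", "migraine")
  has_famhx <- runif(pool_n) < 0.45
  famhx_events <- tibble(
    patient_id = pid[has_famhx],
    days_before_anchor = 0L,
    domain = "famhx",
    variable = "family_history",
    value = NA_real_
  )
  famhx_events$condition <- ifelse(runif(sum(has_famhx)) < 0.8,
                                   sample(qualifying, sum(has_famhx), TRUE),
                                   sample(other_conditions, sum(has_famhx), TRUE))
  famhx_events <- famhx_events %>%
    mutate(variable = .data$condition) %>% select(-"condition")
  demo_events <- tibble(patient_id = pid, days_before_anchor = 0L,
                        domain = "demo", variable = paste0("race_", race),
                        value = 1)

  frail <- frailty_score(
    dx_events %>% mutate(variable = substr(.data$variable, 1, 3)),
    frailty_weights_synthetic()
  )
  frailty <- setNames(rep(0, pool_n), pid)
  frailty[frail$patient_id] <- frail$frailty

  labels <- assign_outcomes(A, spec$outcome_coefs, seed = spec$seed + 1L,
                            target_prevalence = 1 / (1 + spec$control_ratio))

  candidates <- tibble(patient_id = pid,
                       label = ifelse(labels == 1, "case", "control"),
                       sex = sex, age = as.numeric(age),
                       frailty = unname(frailty[pid]))
  matched <- match_controls(candidates, ratio = spec$control_ratio,
                            age_tol = 2, frailty_tol = 2)
  n_sets <- length(unique(matched$matched_set_id))
  if (n_sets > spec$n_cases) {
    matched <- matched %>% filter(.data$matched_set_id <= spec$n_cases)
  } else if (n_sets < spec$n_cases) {
    warn(sprintf("only %d of %d requested matched sets could be formed",
                 n_sets, spec$n_cases))
  }

  set.seed(spec$seed + 2L)
  sets <- unique(matched$matched_set_id)
  train_sets <- sample(sets, size = round(0.7 * length(sets)))
  cohort <- matched %>%
    mutate(split = ifelse(.data$matched_set_id %in% train_sets,
                          "train", "test")) %>%
    arrange(.data$matched_set_id, dplyr::desc(.data$label == "case"),
            .data$patient_id)

  events <- bind_rows(lab_events, dx_events, rx_events, famhx_events,
                      demo_events) %>%
    semi_join(cohort, by = "patient_id") %>%
    arrange(.data$patient_id, .data$days_before_anchor,
            .data$domain, .data$variable)

  kept_idx <- pat_index[cohort$patient_id]
  phenotypes <- lapply(seq_len(R), function(r) {
    list(patient_loading = setNames(A[kept_idx, r], cohort$patient_id),
         time_profile = B[, r],
         lab_profile = setNames(C_lab[, r], lab_names),
         dxrx_profile = setNames(C_dxrx[, r], c(dx_names, rx_names)))
  })

  list(events = events, cohort = as_tibble(cohort), phenotypes = phenotypes)
}

#' Qualifying family-history terms for cardiovascular disease
#'
#' The default list of familial conditions that set the binary cardiac
#' family-history flag.
#' @return Character vector of condition names.
#' @export
cardiac_family_history_terms <- function() {
  c("heart disease", "heart attack", "coronary artery disease",
    "heart failure", "heart defect", "aortic disease",
    "sudden cardiac death", "cardiomyopathy", "cardiovascular disease",
    "rheumatic heart disease")
}
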