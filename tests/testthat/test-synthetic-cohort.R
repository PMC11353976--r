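test_that("cohort_spec validates its invariants", {
  expect_s3_class(cohort_spec(n_cases = 5), "cohort_spec")
  expect_error(cohort_spec(n_cases = 0), "counts")
  expect_error(cohort_spec(years = 0), "years")
  expect_error(cohort_spec(missing_prob = 1.5), "missing_prob")
  expect_error(cohort_spec(n_lab_features = 2, planted_rank = 3,
                           outcome_coefs = c(1, 0, 0)), "planted_rank")
  expect_error(cohort_spec(planted_rank = 2, outcome_coefs = 1), "length")
})

test_that("identical spec and seed give identical cohorts", {
  sp <- cohort_spec(n_cases = 20, n_lab_features = 5, n_dx_features = 6,
                    n_rx_features = 3, planted_rank = 2,
                    outcome_coefs = c(1, 0), seed = 5)
  d1 <- generate_cohort(sp)
  d2 <- generate_cohort(sp)
  expect_identical(d1$events, d2$events)
  expect_identical(d1$cohort, d2$cohort)
  expect_identical(d1$phenotypes, d2$phenotypes)
})

test_that("generated cohort has the requested matched structure and split", {
  sp <- cohort_spec(n_cases = 50, control_ratio = 2, n_lab_features = 5,
                    n_dx_features = 6, n_rx_features = 3, planted_rank = 2,
                    outcome_coefs = c(1.5, 0), seed = 2)
  d <- generate_cohort(sp)
  expect_equal(nrow(d$cohort), 150)
  sizes <- table(d$cohort$matched_set_id)
  expect_length(sizes, 50)
  expect_true(all(sizes == 3))
  per_set <- tapply(d$cohort$label, d$cohort$matched_set_id,
                    function(l) sum(l == "case"))
  expect_true(all(per_set == 1))
  # split is by matched set, roughly 70/30
  split_by_set <- tapply(d$cohort$split, d$cohort$matched_set_id, unique)
  expect_true(all(lengths(split_by_set) == 1))
  expect_equal(sum(split_by_set == "train"), 35)
  # events only for cohort patients, inside the window
  expect_true(all(d$events$patient_id %in% d$cohort$patient_id))
  expect_true(all(d$events$days_before_anchor >= 0 &
                    d$events$days_before_anchor <= 365 * sp$years))
})

test_that("every matched set satisfies the matching tolerances", {
  sp <- cohort_spec(n_cases = 60, n_lab_features = 5, n_dx_features = 6,
                    n_rx_features = 3, planted_rank = 2,
                    outcome_coefs = c(1.5, 0), seed = 9)
  d <- generate_cohort(sp)
  ok <- d$cohort %>%
    dplyr::group_by(matched_set_id) %>%
    dplyr::summarise(
      sex_ok = dplyr::n_distinct(sex) == 1,
      age_ok = max(abs(age - age[label == "case"])) <= 2,
      fr_ok = max(abs(frailty - frailty[label == "case"])) <= 2)
  expect_true(all(ok$sex_ok & ok$age_ok & ok$fr_ok))
})

test_that("outcome assignment hits the target prevalence and effect direction", {
  set.seed(1)
  n <- 2000
  # zero coefficients: prevalence within 3 binomial SEs of the 1/3 target
  mem <- matrix(rgamma(n * 2, 2, 2), n, 2)
  lab0 <- assign_outcomes(mem, c(0, 0), seed = 4, target_prevalence = 1 / 3)
  se <- sqrt(1 / 3 * 2 / 3 / n)
  expect_lt(abs(mean(lab0) - 1 / 3), 3 * se)
  # strong positive coefficient on a binary membership raises prevalence
  memb <- cbind(rbinom(n, 1, 0.5))
  lab1 <- assign_outcomes(memb, 5, seed = 4, target_prevalence = 1 / 3)
  expect_gt(mean(lab1[memb == 1]), mean(lab1[memb == 0]))
  # all-zero memberships: labels depend only on the intercept
  z1 <- assign_outcomes(matrix(0, n, 3), c(1, 2, 3), seed = 7)
  z2 <- assign_outcomes(matrix(0, n, 3), c(-1, 0, 5), seed = 7)
  expect_identical(as.integer(z1), as.integer(z2))
  expect_error(assign_outcomes(mem, c(1, 2, 3), seed = 1), "length")
  expect_error(assign_outcomes(-mem, c(0, 0), seed = 1), "non-negative")
})

test_that("membership-label association is positive under a positive effect", {
  cors <- sapply(1:5, function(s) {
    set.seed(s)
    mem <- matrix(rgamma(1500, 2, 2), ncol = 1)
    lab <- assign_outcomes(mem, 2, seed = s + 100)
    cor(mem[, 1], lab)
  })
  expect_gt(mean(cors), 0)
  expect_true(all(cors > 0))
})

test_that("greedy matching honours tolerances and drops unmatchable cases", {
  cand <- tibble::tibble(
    patient_id = sprintf("C%02d", 1:13),
    label = c(rep("case", 3), rep("control", 10)),
    sex = c("M", "F", "M", rep("M", 6), rep("F", 4)),
    age = c(60, 55, 70, 59, 61, 62, 58, 69, 71, 80, 54, 56, 53),
    frailty = c(2, 1, 3, 2, 3, 1, 2, 4, 2, 3, 1, 2, 0))
  m <- match_controls(cand, ratio = 2, age_tol = 2, frailty_tol = 2)
  # brute-force reference: same case order, exhaustive nearest-first choice
  ref_pool <- cand[cand$label == "control", ]
  picked <- list()
  for (cs_id in sort(cand$patient_id[cand$label == "case"])) {
    cs <- cand[cand$patient_id == cs_id, ]
    elig <- ref_pool[ref_pool$sex == cs$sex &
                       abs(ref_pool$age - cs$age) <= 2 &
                       abs(ref_pool$frailty - cs$frailty) <= 2, ]
    if (nrow(elig) < 2) next
    elig <- elig[order(abs(elig$age - cs$age), abs(elig$frailty - cs$frailty),
                       elig$patient_id), ]
    take <- elig$patient_id[1:2]
    picked[[cs_id]] <- take
    ref_pool <- ref_pool[!ref_pool$patient_id %in% take, ]
  }
  for (cs_id in names(picked)) {
    set <- m$patient_id[m$matched_set_id ==
                          m$matched_set_id[m$patient_id == cs_id]]
    expect_setequal(setdiff(set, cs_id), picked[[cs_id]])
  }
  # a case with no eligible controls is excluded entirely
  lone <- tibble::tibble(patient_id = c("A", "B"), label = c("case", "control"),
                         sex = c("M", "F"), age = c(60, 60), frailty = c(0, 0))
  expect_equal(nrow(match_controls(lone, ratio = 1)), 0)
  expect_error(match_controls(lone, ratio = 0), "ratio")
  expect_error(match_controls(lone[0, ], ratio = 1), "empty")
})

test_that("frailty score sums weights of distinct mapped codes", {
  wm <- tibble::tibble(code = "F00", weight = 7.1)
  expect_equal(nrow(frailty_score(tibble::tibble(patient_id = character(),
                                                 variable = character()), wm)),
               0)
  dup <- event_row(rep("P1", 5), 0, "dx", rep("F00", 5))
  expect_equal(frailty_score(dup, wm)$frailty, 7.1)
  two <- event_row(c("P1", "P1"), 0, "dx", c("F00", "I10"))
  expect_equal(frailty_score(two, wm)$frailty, 7.1)  # I10 unmapped -> 0
  shipped <- frailty_weights_synthetic()
  expect_true(all(c("code", "weight") %in% names(shipped)))
  expect_equal(shipped$weight[shipped$code == "F00"], 7.1)
})

test_that("noiseless single-phenotype cohorts yield an exactly low-rank lab tensor", {
  sp <- cohort_spec(n_cases = 15, control_ratio = 2, n_lab_features = 4,
                    n_dx_features = 4, n_rx_features = 2, planted_rank = 1,
                    encounter_rate = 25, missing_prob = 0, noise_sd = 0,
                    outcome_coefs = 1, seed = 11)
  d <- generate_cohort(sp)
  lv <- build_labvital_tensor(d$events, d$cohort,
                              quintiles = fit_quintiles(d$events,
                                                        d$cohort$patient_id),
                              discretize = FALSE)
  m <- nncp_hals(lv, rank = 1, seed = 1, max_iter = 500, tol = 1e-14)
  expect_lt(m$rel_error, 1e-4)
})
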