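n18 <- tibble::tibble(code = "N18", system = "ICD10")

test_that("spec validation rejects malformed definitions", {
  expect_error(algorithm_spec("x", n18[0, ]), "non-empty")
  expect_error(algorithm_spec("x", dplyr::bind_rows(n18, n18)), "unique")
  expect_error(algorithm_spec("x", tibble::tibble(code = "N18", system = "ICD9")),
               "unknown coding system")
  expect_error(algorithm_spec("x", n18, min_occurrences = 0), ">= 1")
})

test_that("look-back window is [index - 5y, index): edges behave as stated", {
  ch <- toy_cohort("A", "2010-06-01")
  spec1 <- algorithm_spec("ckd", n18)

  near_edge <- code_row("A", d("2010-06-01") - round(4.9 * 365.25), "N18")
  expect_true(flag_patients(ch, near_edge, spec1)$positive)

  on_index <- code_row("A", "2010-06-01", "N18")
  expect_false(flag_patients(ch, on_index, spec1)$positive)
  spec_closed <- algorithm_spec("ckd", n18, include_index = TRUE)
  expect_true(flag_patients(ch, on_index, spec_closed)$positive)

  at_start <- code_row("A", d("2010-06-01") %m-% lubridate::years(5), "N18")
  expect_true(flag_patients(ch, at_start, spec1)$positive)
  before_start <- code_row("A", d("2010-06-01") %m-% lubridate::years(5) - 1,
                           "N18")
  expect_false(flag_patients(ch, before_start, spec1)$positive)
})

test_that("ICD-10 matching is prefix-based at catalog granularity", {
  ch <- toy_cohort("A", "2010-06-01")
  child <- code_row("A", "2008-01-01", "I120")
  i12 <- tibble::tibble(code = "I12", system = "ICD10")
  expect_true(flag_patients(ch, child, algorithm_spec("x", i12))$positive)
  expect_false(flag_patients(ch, child,
                             algorithm_spec("x", i12,
                                            icd10_match = "exact"))$positive)
  # OHIP codes always match exactly, and systems never cross
  ohip403 <- tibble::tibble(code = "403", system = "OHIP")
  expect_false(flag_patients(ch, code_row("A", "2008-01-01", "4030", "OHIP"),
                             algorithm_spec("x", ohip403))$positive)
  expect_false(flag_patients(ch, code_row("A", "2008-01-01", "403", "ICD10"),
                             algorithm_spec("x", ohip403))$positive)
  expect_error(flag_patients(ch, code_row("A", "2008-01-01", "N18", "SNOMED"),
                             algorithm_spec("x", n18)),
               "unknown coding system")
})

test_that("occurrence counting pools codes on distinct days", {
  ch <- toy_cohort("A", "2010-06-01")
  two_codes <- algorithm_spec("x", dplyr::bind_rows(
    n18, tibble::tibble(code = "585", system = "OHIP")
  ), min_occurrences = 2)

  one_code_once <- code_row("A", "2008-01-01", "N18")
  expect_false(flag_patients(ch, one_code_once, two_codes)$positive)

  # same code twice on the same day counts once
  same_day <- dplyr::bind_rows(one_code_once, one_code_once)
  expect_false(flag_patients(ch, same_day, two_codes)$positive)
  spec_records <- algorithm_spec("x", n18, min_occurrences = 2,
                                 count = "records")
  expect_true(flag_patients(ch, same_day, spec_records)$positive)

  # two different codes on different days count as two
  two_days <- dplyr::bind_rows(one_code_once,
                               code_row("A", "2008-02-01", "585", "OHIP"))
  expect_true(flag_patients(ch, two_days, two_codes)$positive)

  # prefix children of one category on one day still count once
  children <- dplyr::bind_rows(code_row("A", "2008-01-01", "N183"),
                               code_row("A", "2008-01-01", "N184"))
  expect_false(flag_patients(ch, children, two_codes)$positive)
})

test_that("flag_patients agrees with the brute-force per-patient oracle", {
  set.seed(61)
  alphabet <- dplyr::bind_rows(
    tibble::tibble(code = c("N18", "N19", "I12", "E112", "N08"),
                   system = "ICD10"),
    tibble::tibble(code = c("403", "585"), system = "OHIP")
  )
  for (rep in 1:8) {
    n <- sample(20:60, 1)
    ids <- sprintf("P%02d", seq_len(n))
    ch <- toy_cohort(ids, rep("2010-06-01", n))
    k <- sample(0:150, 1)
    pick <- alphabet[sample.int(nrow(alphabet), k, replace = TRUE), ]
    codes <- tibble::tibble(
      patient_id = sample(ids, k, replace = TRUE),
      code_date = d("2010-06-01") + sample(-2200:50, k, replace = TRUE),
      code = ifelse(pick$system == "ICD10" & runif(k) < 0.5,
                    paste0(pick$code, sample(0:9, k, replace = TRUE)),
                    pick$code),
      system = pick$system
    )
    spec <- algorithm_spec(
      "rand",
      alphabet[sample.int(nrow(alphabet), sample(1:5, 1)), ],
      lookback_years = sample(c(1, 3, 5), 1),
      min_occurrences = sample(1:3, 1),
      icd10_match = sample(c("prefix", "exact"), 1),
      count = sample(c("distinct_days", "records"), 1),
      include_index = sample(c(TRUE, FALSE), 1)
    )
    expect_equal(flag_patients(ch, codes, spec), oracle_flag(ch, codes, spec),
                 label = sprintf("instance %d", rep))
  }
})

test_that("unions and occurrence thresholds move metrics monotonically", {
  b <- simulate_cohort(sim_params(3000, seed = 62))
  ch <- accrue(b$patients, b$prescriptions, b$labs, b$events)
  ref <- reference_standard(ch, b$labs)
  catalog <- ckd_final_codes()

  sub <- algorithm_spec("sub", catalog[c(5, 8), c("code", "system")])
  full <- algorithm_spec("full", catalog[c(5, 8, 11), c("code", "system")])
  m_sub <- metrics(contingency(flag_patients(ch, b$codes, sub), ref),
                   warn_null = FALSE)
  m_full <- metrics(contingency(flag_patients(ch, b$codes, full), ref),
                    warn_null = FALSE)
  expect_gte(m_full$estimates$sensitivity, m_sub$estimates$sensitivity)
  expect_lte(m_full$estimates$specificity, m_sub$estimates$specificity)

  k1 <- algorithm_spec("k1", catalog[c("code", "system")], min_occurrences = 1)
  k2 <- algorithm_spec("k2", catalog[c("code", "system")], min_occurrences = 2)
  f1 <- flag_patients(ch, b$codes, k1)
  f2 <- flag_patients(ch, b$codes, k2)
  expect_true(all(f1$positive[f2$positive]))  # positives(k=2) within positives(k=1)
  m1 <- metrics(contingency(f1, ref), warn_null = FALSE)
  m2 <- metrics(contingency(f2, ref), warn_null = FALSE)
  expect_lte(m2$estimates$sensitivity, m1$estimates$sensitivity)
  expect_gte(m2$estimates$specificity, m1$estimates$specificity)
})

test_that("single-code evaluation identifies perfect and null emitters", {
  b <- simulate_cohort(sim_params(800, seed = 63,
                                  code_emission = flat_emission(n18, 1, 0)))
  ch <- accrue(b$patients, b$prescriptions, b$labs, b$events)
  ref <- reference_standard(ch, b$labs)
  perf <- evaluate_single_codes(ch, b$codes, n18, ref)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)

  none <- evaluate_single_codes(ch, b$codes[0, ], n18, ref)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  expect_true(is.na(none$ppv))
  prev <- mean(ref$lt45)
  expect_equal(none$npv, 1 - prev)
})

test_that("recovered single-code sensitivities match known emission rates", {
  codes2 <- dplyr::bind_rows(n18, tibble::tibble(code = "585", system = "OHIP"))
  em <- dplyr::bind_rows(flat_emission(n18, 0.3, 0.02),
                         flat_emission(codes2[2, ], 0.15, 0.05))
  b <- simulate_cohort(sim_params(8000, seed = 64, code_emission = em))
  ch <- accrue(b$patients, b$prescriptions, b$labs, b$events)
  ref <- reference_standard(ch, b$labs)
  perf <- evaluate_single_codes(ch, b$codes, codes2, ref)
  n_dis <- sum(ref$lt45)
  # within 3 binomial SDs of the generating probabilities
  expect_lt(abs(perf$sensitivity[1] - 0.3), 3 * sqrt(0.3 * 0.7 / n_dis))
  expect_lt(abs(perf$sensitivity[2] - 0.15), 3 * sqrt(0.15 * 0.85 / n_dis))
  expect_lt(abs((1 - perf$specificity[1]) - 0.02),
            3 * sqrt(0.02 * 0.98 / (nrow(ref) - n_dis)))
})

test_that("algorithm assembly applies the sensitivity rule plus manual adds", {
  perf <- tibble::tibble(
    code = ckd_final_codes()$code,
    system = ckd_final_codes()$system,
    sensitivity = c(0.0017, 0.0555, 0.0001, 0.0086, 0.0720, 0.0049, 0.0375,
                    0.1224, 0.0451, 0.0308, 0.2239)
  )
  built <- build_algorithm(perf, min_sensitivity = 0.03,
                           manual_includes = c("E102", "E132", "E142", "I13"),
                           name = "ckd_final")
  expect_setequal(paste(built$codes$code, built$codes$system),
                  paste(ckd_final_codes()$code, ckd_final_codes()$system))
  expect_equal(nrow(built$codes), 11)

  all_in <- build_algorithm(perf, min_sensitivity = 0)
  expect_equal(nrow(all_in$codes), nrow(perf))
  expect_error(build_algorithm(perf, min_sensitivity = 0.5), "no codes selected")
})

test_that("the shipped YAML definition matches the built-in catalog", {
  path <- system.file("extdata", "ckd_final.yaml", package = "ckdcodes")
  spec <- read_algorithm(path)
  expect_equal(spec$name, "ckd_final")
  expect_equal(spec$lookback_years, 5)
  expect_equal(spec$min_occurrences, 1L)
  expect_equal(spec$codes, ckd_final_codes()[c("code", "system")])
  spec2 <- read_algorithm(path, min_occurrences = 2)
  expect_equal(spec2$min_occurrences, 2L)
})
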