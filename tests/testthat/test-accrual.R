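cfg <- accrual_config(accrual_start = "2008-01-01", accrual_end = "2009-12-31")

test_that("clean path: eligible prescription becomes the index", {
  ch <- accrue(
    patient_row("A", "F", "1938-03-01"),            # 70 at index
    rx_row("A", "2008-06-01"),
    lab_row("A", "2008-05-02"),                     # 30 days prior
    empty_events(), cfg
  )
  expect_equal(nrow(ch), 1)
  expect_true(ch$included)
  expect_equal(ch$index_date, d("2008-06-01"))
  expect_equal(ch$age_at_index, 70L)
  expect_true(is.na(ch$exclusion_reason))
})

test_that("lab window is (index - 365, index]: 400 days is too old, same day counts", {
  old_lab <- accrue(patient_row("A"), rx_row("A", "2008-06-01"),
                    lab_row("A", d("2008-06-01") - 400), empty_events(), cfg)
  expect_false(old_lab$included)
  expect_equal(as.character(old_lab$exclusion_reason), "no_baseline_lab")

  same_day <- accrue(patient_row("A"), rx_row("A", "2008-06-01"),
                     lab_row("A", "2008-06-01"), empty_events(), cfg)
  expect_true(same_day$included)

  boundary <- accrue(patient_row("A"), rx_row("A", "2008-06-01"),
                     lab_row("A", d("2008-06-01") - 365), empty_events(), cfg)
  expect_false(boundary$included)  # exactly 365 days prior is outside
})

test_that("three-patient toy set reproduces the hand-traced tally", {
  patients <- dplyr::bind_rows(patient_row("A"), patient_row("B"),
                               patient_row("C", birth = "1943-06-15"))  # C under 66
  rx <- dplyr::bind_rows(rx_row("A", "2008-06-01"), rx_row("B", "2008-06-01"),
                         rx_row("C", "2008-06-01"))
  labs <- dplyr::bind_rows(lab_row("A", "2008-05-02"), lab_row("B", "2008-05-02"),
                           lab_row("C", "2008-05-02"))
  events <- event_row("B", "dialysis", d("2008-06-01") - 100)
  ch <- accrue(patients, rx, labs, events, cfg)
  expect_equal(sum(ch$included), 1)
  tally <- exclusion_tally(ch)
  expect_equal(tally$n[tally$reason == "dialysis"], 1L)
  expect_equal(tally$n[tally$reason == "age"], 1L)
  expect_equal(sum(tally$n), 2L)
})

test_that("hospitalization washout follows the configured reading", {
  patients <- patient_row("A")
  rx <- rx_row("A", "2008-06-01")
  labs <- lab_row("A", "2008-05-02")
  overlap <- event_row("A", "hospitalization", "2008-05-25",
                       d("2008-06-01") - 2)
  ended_earlier <- event_row("A", "hospitalization", "2008-05-20", "2008-05-27")

  ch <- accrue(patients, rx, labs, overlap, cfg)
  expect_false(ch$included)
  expect_equal(as.character(ch$exclusion_reason), "hospitalization")

  ch2 <- accrue(patients, rx, labs, ended_earlier, cfg)
  expect_true(ch2$included)

  # alternative reading: the washout invalidates the lab, not the accrual
  cfg_lab <- accrual_config(accrual_start = "2008-01-01",
                            accrual_end = "2009-12-31",
                            hospitalization_rule = "exclude_lab")
  ch3 <- accrue(patients, rx, labs, overlap, cfg_lab)
  expect_false(ch3$included)
  expect_equal(as.character(ch3$exclusion_reason), "no_baseline_lab")
})

test_that("dialysis and transplant look-backs use open windows before the index", {
  base <- list(patient_row("A"), rx_row("A", "2008-06-01"),
               lab_row("A", "2008-05-02"))
  run <- function(ev) accrue(base[[1]], base[[2]], base[[3]], ev, cfg)

  expect_false(run(event_row("A", "dialysis", d("2008-06-01") - 100))$included)
  # dialysis exactly 365 days prior is outside the open window
  expect_true(run(event_row("A", "dialysis", d("2008-06-01") - 365))$included)
  # dialysis on the index date does not count
  expect_true(run(event_row("A", "dialysis", "2008-06-01"))$included)

  expect_false(run(event_row("A", "transplant", "2004-01-01"))$included)
  # transplant more than five years before is allowed
  expect_true(run(event_row("A", "transplant", "2003-05-31"))$included)
})

test_that("a later prescription can qualify when the first fails", {
  patients <- patient_row("A")
  rx <- dplyr::bind_rows(rx_row("A", "2008-02-01"), rx_row("A", "2008-06-01"))
  labs <- lab_row("A", "2008-05-02")  # after first rx, before second
  ch <- accrue(patients, rx, labs, empty_events(), cfg)
  expect_true(ch$included)
  expect_equal(ch$index_date, d("2008-06-01"))
  expect_equal(nrow(ch), 1)  # selected once

  # prescriptions outside the accrual window are skipped, not errors
  rx2 <- dplyr::bind_rows(rx_row("A", "2006-01-01"), rx)
  expect_identical(accrue(patients, rx2, labs, empty_events(), cfg)$index_date,
                   ch$index_date)
})

test_that("patients with no in-window prescription do not appear", {
  ch <- accrue(patient_row("A"), rx_row("A", "2006-01-01"),
               lab_row("A", "2005-12-20"), empty_events(), cfg)
  expect_equal(nrow(ch), 0)
})

test_that("output is independent of input row order", {
  b <- simulate_cohort(sim_params(500, seed = 41))
  ch1 <- accrue(b$patients, b$prescriptions, b$labs, b$events)
  set.seed(1)
  shuffle <- function(df) df[sample.int(nrow(df)), , drop = FALSE]
  ch2 <- accrue(shuffle(b$patients), shuffle(b$prescriptions),
                shuffle(b$labs), shuffle(b$events))
  expect_identical(as.data.frame(ch1), as.data.frame(ch2))
})

test_that("included plus excluded equals patients with an in-window prescription", {
  b <- simulate_cohort(sim_params(800, seed = 42))
  ch <- accrue(b$patients, b$prescriptions, b$labs, b$events)
  in_window <- unique(b$prescriptions$patient_id[
    b$prescriptions$rx_date >= accrual_config()$accrual_start &
      b$prescriptions$rx_date <= accrual_config()$accrual_end])
  expect_setequal(ch$patient_id, in_window)
  expect_equal(sum(ch$included) + sum(exclusion_tally(ch)$n), length(in_window))
})

test_that("shrinking the lab look-back never adds inclusions", {
  b <- simulate_cohort(sim_params(600, seed = 43))
  full <- accrue(b$patients, b$prescriptions, b$labs, b$events,
                 accrual_config(lab_lookback_days = 365))
  short <- accrue(b$patients, b$prescriptions, b$labs, b$events,
                  accrual_config(lab_lookback_days = 120))
  expect_true(all(short$patient_id[short$included] %in%
                    full$patient_id[full$included]))
  expect_lte(sum(short$included), sum(full$included))
})

test_that("unparseable dates fail loudly with the offending row", {
  bad_rx <- tibble::tibble(patient_id = "A", rx_date = "2008-13-45")
  expect_error(accrue(patient_row("A"), bad_rx, empty_labs(), empty_events(),
                      cfg),
               "unparseable date.*rx_date")
})
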