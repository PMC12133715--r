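one_patient_claims <- function(dates, codes, id = "A", source = "HDD") {
  tibble::tibble(
    patient_id = id,
    source = source,
    claim_date = as.Date(dates),
    codes = lapply(codes, as.character)
  )
}

test_that("surveillance window is 12 months, 24 for HER2-positive, 12 under sensitivity", {
  expect_equal(surveillance_start("negative"), 12L)
  expect_equal(surveillance_start("positive"), 24L)
  expect_equal(surveillance_start("missing"), 12L)
  expect_equal(surveillance_start("positive", sensitivity_12m = TRUE), 12L)
  expect_equal(
    surveillance_start(c("negative", "positive")), c(12L, 24L)
  )
  expect_error(surveillance_start("pos"), "her2")
})

test_that("claims inside the primary-treatment window never match", {
  dx <- as.Date("2005-01-01")
  start <- dx + months_to_days(12)
  cl <- one_patient_claims(dx + 61, list("9925")) # chemo at ~2 months
  m <- match_indicators(cl, default_code_set(), start)
  expect_equal(nrow(m), 0)
})

test_that("indicator classes and the start boundary are applied as defined", {
  dx <- as.Date("2005-01-01")
  start <- dx + months_to_days(12)
  # mastectomy procedure at 30 months -> one class-3 match
  cl <- one_patient_claims(dx + months_to_days(30), list("8541"))
  m <- match_indicators(cl, default_code_set(), start)
  expect_equal(m$indicator_class, 3L)
  # claim exactly on the boundary day counts (inclusive)
  cl2 <- one_patient_claims(start, list("9925"))
  expect_equal(nrow(match_indicators(cl2, default_code_set(), start)), 1)
  expect_equal(nrow(match_indicators(
    one_patient_claims(start - 1, list("9925")), default_code_set(), start
  )), 0)
})

test_that("a claim carrying several classes is reported once with the lowest class", {
  dx <- as.Date("2005-01-01")
  start <- dx + months_to_days(12)
  cl <- one_patient_claims(dx + months_to_days(40), list(c("1970", "9229")))
  m <- match_indicators(cl, default_code_set(), start)
  expect_equal(nrow(m), 1)
  expect_equal(m$indicator_class, 2L) # radiotherapy (2) beats secondary neoplasm (4)
})

test_that("malformed ICD-9-CM codes are skipped with a warning, not fatally", {
  dx <- as.Date("2005-01-01")
  start <- dx + months_to_days(12)
  cl <- one_patient_claims(dx + months_to_days(30), list(c("ZZ", "8541xx", "8541")))
  expect_warning(m <- match_indicators(cl, default_code_set(), start), "malformed")
  expect_equal(m$indicator_class, 3L)
})

test_that("earliest indicator wins and empty claim sets yield no recurrence", {
  cohort <- registry_skeleton(1)
  dx <- cohort$diagnosis_date[1]
  claims <- one_patient_claims(
    dx + months_to_days(c(30, 35)), list("8541", "9925"),
    id = cohort$patient_id[1]
  )
  got <- ascertain_recurrence(cohort, claims)
  expect_equal(got$recurrence_date, dx + months_to_days(30))
  expect_equal(got$indicator_class, 3L)
  # only primary-window claims -> none
  early <- one_patient_claims(
    dx + c(40, 200), list("8543", "9925"), id = cohort$patient_id[1]
  )
  expect_equal(nrow(ascertain_recurrence(cohort, early)), 0)
  # no claims at all -> none
  expect_equal(nrow(ascertain_recurrence(cohort, early[0, ])), 0)
})

test_that("ascertainment equals exhaustive search on random small claim sets", {
  cs <- default_code_set()
  pool <- c("9925", "V5811", "9229", "V580", "8541", "1749", "1975", "196",
            "4019", "25000", "V7612", "E8889")
  dx <- as.Date("2005-06-15")
  start <- dx + months_to_days(12)
  for (seed in 1:60) {
    set.seed(seed)
    n_claims <- sample(0:6, 1)
    dates <- dx + sample(30:2000, max(n_claims, 1), TRUE)[seq_len(n_claims)]
    codes <- lapply(seq_len(n_claims), \(i) sample(pool, sample(1:3, 1)))
    cl <- one_patient_claims(dates, codes)
    m <- match_indicators(cl, cs, start)
    want <- oracle_first_indicator(dates, codes, cs, start)
    if (is.na(want$class)) {
      expect_equal(nrow(m), 0)
    } else {
      expect_equal(m$claim_date[1], want$date)
      expect_equal(m$indicator_class[1], want$class)
    }
  }
})

test_that("first-event resolution follows the competing-event hierarchy", {
  cohort <- registry_skeleton(4)
  dx <- cohort$diagnosis_date[1]
  cutoff <- as.Date("2021-12-31")
  # patient 1: recurrence at 30 months, death at 40 months -> recurrence
  cohort$death_date[1] <- dx + months_to_days(40)
  cohort$vital_status[1] <- "dead"
  # patient 2: second primary at 20 months beats recurrence claim at 50 months
  cohort$second_primary_date[2] <- dx + months_to_days(20)
  cohort$second_primary_site[2] <- "C34"
  rec <- tibble::tibble(
    patient_id = cohort$patient_id[1:2],
    recurrence_date = dx + months_to_days(c(30, 50)),
    indicator_class = c(1L, 3L),
    matched_code = c("9925", "8541")
  )
  # patient 4: same-day recurrence and death -> recurrence
  cohort$death_date[4] <- dx + months_to_days(30)
  cohort$vital_status[4] <- "dead"
  rec <- dplyr::bind_rows(rec, tibble::tibble(
    patient_id = cohort$patient_id[4],
    recurrence_date = dx + months_to_days(30),
    indicator_class = 1L, matched_code = "9925"
  ))
  out <- resolve_outcomes(cohort, rec, cutoff)
  expect_equal(out$event, c("recurrence", "second_primary", "admin_censor", "recurrence"))
  expect_equal(out$time_days[1], months_to_days(30))
  expect_equal(out$time_days[2], months_to_days(20))
  expect_equal(out$time_days[3], as.integer(cutoff - dx))
  expect_true(is.na(out$indicator_class[2]))
})

test_that("candidate dates before diagnosis are rejected with the field named", {
  cohort <- registry_skeleton(1)
  cohort$death_date[1] <- cohort$diagnosis_date[1] - 5
  no_rec <- tibble::tibble(
    patient_id = character(), recurrence_date = as.Date(character()),
    indicator_class = integer(), matched_code = character()
  )
  expect_error(
    resolve_outcomes(cohort, no_rec, as.Date("2021-12-31")),
    "death_date"
  )
})

test_that("ascertained recurrences recover the latent truth exactly with exact claims", {
  cfg <- exact_claims_config(n = 2000, seed = 11)
  sim <- simulate_cohort(cfg)
  cohort <- derive_strata(apply_eligibility(sim$registry)$cohort)
  claims <- collect_claims(sim$hdd, sim$ops)
  rec <- ascertain_recurrence(cohort, claims)
  truth <- dplyr::inner_join(sim$truth,
    dplyr::select(cohort, patient_id, diagnosis_date, her2_status),
    by = "patient_id"
  )
  start_days <- months_to_days(surveillance_start(truth$her2_status))
  expected <- truth |>
    dplyr::filter(true_event == "recurrence", true_time_days >= start_days)
  got <- dplyr::inner_join(expected, rec, by = "patient_id")
  # every expected woman detected, on the exact truth date
  expect_equal(nrow(got), nrow(expected))
  expect_true(all(
    got$recurrence_date == got$diagnosis_date + got$true_time_days
  ))
  # and no detections before the subject's surveillance boundary
  all_rec <- dplyr::inner_join(rec,
    dplyr::select(cohort, patient_id, diagnosis_date, her2_status),
    by = "patient_id"
  )
  bound <- months_to_days(surveillance_start(all_rec$her2_status))
  expect_true(all(
    as.numeric(all_rec$recurrence_date - all_rec$diagnosis_date) >= bound
  ))
})
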